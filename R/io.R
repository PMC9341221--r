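config_hash <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(sanitize_for_json(x), tf, auto_unbox = TRUE,
                       digits = NA, pretty = FALSE)
  unname(tools::md5sum(tf))
}

sanitize_for_json <- function(x) {
  if (is.environment(x)) return(NULL)
  if (is.function(x)) return(NULL)
  if (is.list(x)) {
    x <- lapply(x, sanitize_for_json)
    x[!vapply(x, is.null, TRUE)]
  } else if (is.numeric(x)) {
    x[!is.finite(x)] <- NA
    x
  } else x
}

#' Write a run manifest (JSON)
#'
#' Records the configuration echo, its hash, the seed, and run counters so a
#' run can be audited and reproduced.
#'
#' @param fit A \code{contrast_mine} object.
#' @param path Output path.
#' @param extra Optional named list merged into the manifest.
#' @export
write_run_manifest <- function(fit, path, extra = NULL) {
  cfg <- sanitize_for_json(unclass(fit$control))
  manifest <- c(list(config = cfg, config_hash = config_hash(cfg),
                     seed = fit$control$seed,
                     growth_max = fit$growth_max,
                     baseline = list(j_bar = fit$baseline$j_bar,
                                     m_bar = fit$baseline$m_bar,
                                     k = fit$baseline$k),
                     counts = fit$counts[c("evaluated", "mining_calls",
                                           "registry")]),
                extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Export the explored selection tree
#'
#' Writes the node list (canonical key, parent key, layer, J, status) so the
#' explored paths can be audited.
#'
#' @param fit A \code{contrast_mine} object.
#' @param path Output TSV path.
#' @export
write_tree <- function(fit, path) {
  utils::write.table(
    fit$pool[, c("key", "parent", "layer", "j_ori", "n_pair", "status")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genotype calls from a VCF as measurement variables
#'
#' Optional convenience for genotype tables: maps each variant's GT field to
#' a 3-level category (hom-ref / het / hom-alt), one measurement variable per
#' variant, one row per sample. Requires the \pkg{vcfR} package.
#'
#' @param path VCF file path.
#' @return data.frame of categorical genotype columns (samples in rows).
#' @export
read_vcf_measurements <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_vcf_measurements requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  map <- function(g) {
    g <- gsub("|", "/", g, fixed = TRUE)
    out <- rep(NA_character_, length(g))
    out[g %in% "0/0"] <- "hom-ref"
    out[g %in% c("0/1", "1/0")] <- "het"
    out[g %in% "1/1"] <- "hom-alt"
    out
  }
  ids <- rownames(gt)
  out <- as.data.frame(apply(gt, 1L, map), stringsAsFactors = FALSE)
  names(out) <- ids
  rownames(out) <- colnames(gt)
  out
}
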
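#' @keywords internal
"_PACKAGE"

NA_LABEL <- "NA"

#' Declare a variable schema
#'
#' A variable schema assigns a variable its role in the mining process:
#' \emph{population} variables divide subjects into subgroups, while
#' \emph{measurement} variables describe the characteristics (patterns) of
#' those subgroups. Categorical variables carry an explicit category set;
#' numeric variables carry a discretization rule that is applied during
#' encoding.
#'
#' @param name Variable name (must match a column of the subject table).
#' @param role Either \code{"population"} or \code{"measurement"}.
#' @param categories Character vector of category labels (opaque,
#'   case-sensitive). May be \code{NULL} when \code{discretization} is given.
#' @param na_allowed Logical; if \code{TRUE}, missing cells are encoded as the
#'   reserved \code{"NA"} category. \code{"NA"} categories never take part in
#'   subgroup definitions.
#' @param discretization Optional list with elements \code{method} (one of
#'   \code{"equal-width"}, \code{"equal-density"}, \code{"entropy"}) and
#'   \code{bins} (integer >= 2), or \code{thresholds} (numeric cut points).
#' @return A list of class \code{"cm_schema"}.
#' @export
variable_schema <- function(name, role = c("population", "measurement"),
                            categories = NULL, na_allowed = TRUE,
                            discretization = NULL) {
  role <- match.arg(role)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("variable name must be a non-empty string")
  if (is.null(categories) && is.null(discretization))
    stop("variable '", name, "': need explicit categories or a discretization rule")
  if (!is.null(categories)) {
    categories <- as.character(categories)
    if (anyDuplicated(categories))
      stop("variable '", name, "': duplicate categories")
    if (NA_LABEL %in% categories && !na_allowed)
      stop("variable '", name, "': reserved label 'NA' requires na_allowed")
    usable <- setdiff(categories, NA_LABEL)
    if (role == "population" && length(usable) < 2L)
      stop("population variable '", name, "' needs at least 2 non-NA categories")
  }
  if (!is.null(discretization)) {
    method <- discretization$method
    if (is.null(discretization$thresholds)) {
      if (is.null(method) ||
          !method %in% c("equal-width", "equal-density", "entropy"))
        stop("variable '", name, "': unknown discretization method")
      if (is.null(discretization$bins) || discretization$bins < 2L)
        stop("variable '", name, "': discretization needs bins >= 2")
    }
  }
  structure(list(name = name, role = role, categories = categories,
                 na_allowed = isTRUE(na_allowed),
                 discretization = discretization),
            class = "cm_schema")
}

#' Load a data-definition file
#'
#' Reads a structured definition document (JSON or YAML) assigning every
#' variable a role and either an explicit category set or a discretization
#' rule. The document is a mapping from variable name to a record with fields
#' \code{role}, \code{categories}, \code{na_allowed}, \code{discretization};
#' alternatively a list of such records each carrying a \code{name}.
#'
#' @param config Path to a \code{.json}/\code{.yaml}/\code{.yml} file, or an
#'   already-parsed list.
#' @return A named list of \code{cm_schema} objects, class
#'   \code{"cm_definition"}.
#' @export
read_definition <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("definition file not found: ", config)
    ext <- tolower(tools::file_ext(config))
    parsed <- switch(ext,
      "json" = jsonlite::fromJSON(config, simplifyVector = TRUE),
      "yaml" = ,
      "yml" = yaml::read_yaml(config),
      stop("unsupported definition format: .", ext))
  } else if (is.list(config)) {
    parsed <- config
  } else stop("config must be a file path or a list")
  as_definition(parsed)
}

#' @rdname read_definition
#' @param x A list describing variable schemas (see \code{read_definition}).
#' @export
as_definition <- function(x) {
  if (inherits(x, "cm_definition")) return(x)
  if (!is.list(x) || length(x) == 0L) stop("empty or malformed definition")
  entries <- x
  nms <- names(entries)
  if (is.null(nms) || any(!nzchar(nms))) {
    nms <- vapply(entries, function(e) as.character(e$name %||% ""), "")
    if (any(!nzchar(nms))) stop("malformed definition: unnamed variable entry")
  }
  if (anyDuplicated(nms))
    stop("duplicate variable name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  schemas <- vector("list", length(entries))
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    if (is.null(e$role)) stop("variable '", nms[i], "': missing role")
    if (!e$role %in% c("population", "measurement"))
      stop("variable '", nms[i], "': unknown role '", e$role, "'")
    schemas[[i]] <- variable_schema(
      name = nms[i], role = e$role,
      categories = e$categories,
      na_allowed = if (is.null(e$na_allowed)) TRUE else isTRUE(e$na_allowed),
      discretization = e$discretization)
  }
  names(schemas) <- nms
  structure(schemas, class = "cm_definition")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cm_definition <- function(x, ...) {
  roles <- vapply(x, `[[`, "", "role")
  cat("Data definition:", length(x), "variables (",
      sum(roles == "population"), "population,",
      sum(roles == "measurement"), "measurement )\n")
  invisible(x)
}

#' Discretize a numeric vector into categories
#'
#' Supports equal-width bins over \code{[min, max]}, equal-density
#' (equal-frequency) bins whose occupancies differ by at most one after a
#' stable sort, and recursive entropy-based binary splitting that maximizes
#' information gain against a supplied class label (with an MDL-style stop).
#' Missing values receive the reserved label \code{"NA"}.
#'
#' @param values Numeric vector.
#' @param method One of \code{"equal-width"}, \code{"equal-density"},
#'   \code{"entropy"}.
#' @param bins Number of bins (>= 2). For \code{"entropy"} this is an upper
#'   bound on the number of bins.
#' @param class Class labels, required for \code{method = "entropy"}.
#' @param thresholds Explicit cut points; when given, \code{method} and
#'   \code{bins} are ignored.
#' @return Character vector of bin labels (\code{"bin1"}, \code{"bin2"}, ...),
#'   with \code{"NA"} for missing input.
#' @export
discretize <- function(values, method = c("equal-width", "equal-density",
                                          "entropy"),
                       bins = 2L, class = NULL, thresholds = NULL) {
  stopifnot(is.numeric(values))
  out <- rep(NA_LABEL, length(values))
  ok <- !is.na(values)
  v <- values[ok]
  if (length(v) == 0L) return(out)
  if (!is.null(thresholds)) {
    cuts <- sort(unique(as.numeric(thresholds)))
    idx <- findInterval(v, cuts) + 1L
    out[ok] <- paste0("bin", idx)
    return(out)
  }
  method <- match.arg(method)
  bins <- as.integer(bins)
  if (bins < 2L) stop("bins must be >= 2")
  if (method == "equal-width") {
    rng <- range(v)
    if (rng[1] == rng[2]) stop("equal-width discretization of constant input")
    edges <- seq(rng[1], rng[2], length.out = bins + 1L)
    idx <- findInterval(v, edges, rightmost.closed = TRUE, all.inside = TRUE)
    out[ok] <- paste0("bin", idx)
  } else if (method == "equal-density") {
    if (bins > length(unique(v)))
      stop("bins exceeds the number of distinct values")
    ord <- order(v)              # stable sort: ties keep input order
    sizes <- rep(length(v) %/% bins, bins)
    extra <- length(v) %% bins
    if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    idx <- integer(length(v))
    idx[ord] <- rep(seq_len(bins), times = sizes)
    out[ok] <- paste0("bin", idx)
  } else {
    if (is.null(class)) stop("entropy discretization requires class labels")
    cl <- class[ok]
    if (length(cl) != length(v)) stop("class must match values in length")
    cuts <- entropy_cuts(v, cl, max_cuts = bins - 1L)
    idx <- findInterval(v, sort(cuts)) + 1L
    out[ok] <- paste0("bin", idx)
  }
  out
}

entropy_of <- function(cl) {
  p <- table(cl); p <- p[p > 0] / length(cl)
  -sum(p * log2(p))
}

# Recursive binary information-gain splitting with the Fayyad-Irani
# MDL-style acceptance criterion; returns the accepted cut points.
entropy_cuts <- function(v, cl, max_cuts) {
  if (max_cuts <= 0L) return(numeric(0))
  ord <- order(v)
  v <- v[ord]; cl <- as.character(cl)[ord]
  n <- length(v)
  if (n < 2L) return(numeric(0))
  cand <- unique((v[-n] + v[-1L])[v[-n] != v[-1L]] / 2)
  if (length(cand) == 0L) return(numeric(0))
  base <- entropy_of(cl)
  best_gain <- -Inf; best_cut <- NA_real_
  for (cut in cand) {
    left <- cl[v <= cut]; right <- cl[v > cut]
    e <- (length(left) * entropy_of(left) +
          length(right) * entropy_of(right)) / n
    gain <- base - e
    if (gain > best_gain) { best_gain <- gain; best_cut <- cut }
  }
  left <- cl[v <= best_cut]; right <- cl[v > best_cut]
  k <- length(unique(cl)); k1 <- length(unique(left)); k2 <- length(unique(right))
  delta <- log2(3^k - 2) - (k * entropy_of(cl) - k1 * entropy_of(left) -
                            k2 * entropy_of(right))
  accept <- best_gain > (log2(n - 1) + delta) / n
  if (!accept) return(numeric(0))
  lcuts <- entropy_cuts(v[v <= best_cut], left, max_cuts - 1L)
  rcuts <- entropy_cuts(v[v > best_cut], right, max_cuts - 1L - length(lcuts))
  c(lcuts, best_cut, rcuts)
}

#' Encode a raw subject table into a mineable dataset
#'
#' Maps every cell of the subject-per-row table onto the declared category
#' set of its variable, applying discretization rules where present. Rows
#' whose missing rate exceeds \code{max_missing} are dropped; remaining
#' missing cells become the reserved \code{"NA"} category where allowed.
#'
#' @param table A data.frame (one row per subject, one column per declared
#'   variable).
#' @param definition A \code{cm_definition} (see \code{\link{read_definition}}).
#' @param max_missing Ceiling on the per-row fraction of missing cells;
#'   rows above it are omitted (default 0.5).
#' @return An object of class \code{"cm_data"}: integer-coded record matrix
#'   plus schemas. The number of dropped rows is in \code{$dropped}.
#' @export
encode_dataset <- function(table, definition, max_missing = 0.5) {
  definition <- as_definition(definition)
  missing_cols <- setdiff(names(definition), colnames(table))
  if (length(missing_cols))
    stop("table lacks declared column(s): ",
         paste(missing_cols, collapse = ", "))
  vars <- names(definition)
  raw <- table[, vars, drop = FALSE]

  # apply discretization rules, fixing the realized category sets
  cells <- vector("list", length(vars)); names(cells) <- vars
  for (v in vars) {
    sch <- definition[[v]]
    col <- raw[[v]]
    if (!is.null(sch$discretization)) {
      d <- sch$discretization
      lab <- discretize(as.numeric(col),
                        method = d$method %||% "equal-width",
                        bins = d$bins %||% 2L,
                        class = if (!is.null(d$class_from))
                          raw[[d$class_from]] else NULL,
                        thresholds = d$thresholds)
      nb <- if (!is.null(d$thresholds)) length(d$thresholds) + 1L
            else as.integer(d$bins %||% 2L)
      definition[[v]]$categories <- paste0("bin", seq_len(nb))
      cells[[v]] <- lab
    } else {
      cells[[v]] <- as.character(col)
    }
  }

  # row-level missing policy
  miss <- vapply(vars, function(v) {
    is.na(cells[[v]]) | cells[[v]] == NA_LABEL
  }, logical(nrow(raw)))
  if (is.null(dim(miss))) miss <- matrix(miss, nrow = 1L)
  rate <- rowMeans(miss)
  keep <- rate <= max_missing
  dropped <- sum(!keep)

  n <- sum(keep)
  x <- matrix(0L, nrow = n, ncol = length(vars),
              dimnames = list(NULL, vars))
  for (v in vars) {
    sch <- definition[[v]]
    cats <- sch$categories
    if (sch$na_allowed && !(NA_LABEL %in% cats)) cats <- c(cats, NA_LABEL)
    definition[[v]]$categories <- cats
    val <- cells[[v]][keep]
    val[is.na(val)] <- NA_LABEL
    code <- match(val, cats)
    if (anyNA(code)) {
      bad <- unique(val[is.na(code)])
      stop("variable '", v, "': value(s) not covered by declared categories: ",
           paste(utils::head(bad, 5L), collapse = ", "))
    }
    if (!sch$na_allowed && any(val == NA_LABEL))
      stop("variable '", v, "': missing values present but na_allowed is FALSE")
    x[, v] <- code
  }
  roles <- vapply(definition, `[[`, "", "role")
  structure(list(x = x, schema = definition,
                 pop_vars = vars[roles == "population"],
                 meas_vars = vars[roles == "measurement"],
                 n = n, dropped = dropped),
            class = "cm_data")
}

#' @export
print.cm_data <- function(x, ...) {
  cat("Encoded dataset:", x$n, "records,",
      length(x$pop_vars), "population +",
      length(x$meas_vars), "measurement variables")
  if (x$dropped > 0) cat(" (", x$dropped, "rows dropped for missingness)")
  cat("\n")
  invisible(x)
}

#' Decode a cm_data object back to labels
#' @param data A \code{cm_data} object.
#' @return data.frame of category labels.
#' @export
decode_dataset <- function(data) {
  stopifnot(inherits(data, "cm_data"))
  out <- as.data.frame(lapply(colnames(data$x), function(v) {
    data$schema[[v]]$categories[data$x[, v]]
  }), optional = TRUE, stringsAsFactors = FALSE)
  names(out) <- colnames(data$x)
  out
}

#' Read a subject table (CSV or TSV by extension)
#' @param path File path; \code{.csv} is comma-separated, anything else
#'   tab-separated. A header row of variable names is required.
#' @return data.frame of character columns.
#' @export
read_subject_table <- function(path) {
  if (!file.exists(path)) stop("subject table not found: ", path)
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, colClasses = "character",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    na.strings = character(0))
}

#' Write an encoded dataset as TSV (category labels)
#' @param data A \code{cm_data} object.
#' @param path Output path.
#' @export
write_dataset <- function(data, path) {
  utils::write.table(decode_dataset(data), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
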
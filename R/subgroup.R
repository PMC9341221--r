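#' Build a contrast pair from a population variable
#'
#' A contrast pair \code{(v, a, b)} opposes two distinct non-NA categories of
#' one population variable; its identity is unordered: \code{(v, a, b)} and
#' \code{(v, b, a)} denote the same pair.
#'
#' @param variable Population variable name.
#' @param cat_a,cat_b Two distinct category labels; neither may be the
#'   reserved \code{"NA"} label.
#' @return Object of class \code{"contrast_pair"}.
#' @export
contrast_pair <- function(variable, cat_a, cat_b) {
  cat_a <- as.character(cat_a); cat_b <- as.character(cat_b)
  if (identical(cat_a, cat_b))
    stop("a contrast pair needs two distinct categories")
  if (NA_LABEL %in% c(cat_a, cat_b))
    stop("'NA' categories are never used to form subgroups")
  structure(list(variable = as.character(variable),
                 cat_a = cat_a, cat_b = cat_b),
            class = "contrast_pair")
}

#' @export
format.contrast_pair <- function(x, ...) {
  paste0(x$variable, ":", x$cat_a, "<->", x$cat_b)
}

#' @export
print.contrast_pair <- function(x, ...) {
  cat(format(x), "\n"); invisible(x)
}

#' All contrast pairs of a population variable
#'
#' Composes every unordered pair of distinct non-NA categories; the count is
#' \code{choose(c, 2)} for \code{c} usable categories.
#'
#' @param schema A \code{cm_schema} with role \code{"population"}.
#' @return List of \code{contrast_pair} objects.
#' @export
make_contrast_pairs <- function(schema) {
  stopifnot(inherits(schema, "cm_schema"))
  if (schema$role != "population")
    stop("contrast pairs are formed from population variables only")
  cats <- setdiff(schema$categories, NA_LABEL)
  if (length(cats) < 2L)
    stop("variable '", schema$name, "' has fewer than 2 usable categories")
  idx <- utils::combn(length(cats), 2L)
  lapply(seq_len(ncol(idx)), function(j) {
    contrast_pair(schema$name, cats[idx[1L, j]], cats[idx[2L, j]])
  })
}

#' Construct a contrast subgroup pair
#'
#' A contrast subgroup pair is an ordered conjunction of contrast pairs over
#' distinct population variables: side 1 is defined by the \code{cat_a}
#' categories in positional correspondence, side 2 by the \code{cat_b}
#' categories.
#'
#' @param ... \code{contrast_pair} objects (or a single list of them).
#' @return Object of class \code{"contrast_subgroup"}.
#' @export
contrast_subgroup <- function(...) {
  pairs <- list(...)
  if (length(pairs) == 1L && !inherits(pairs[[1L]], "contrast_pair"))
    pairs <- pairs[[1L]]
  if (length(pairs) == 0L)
    return(structure(list(vars = character(0), a = character(0),
                          b = character(0)), class = "contrast_subgroup"))
  stopifnot(all(vapply(pairs, inherits, TRUE, "contrast_pair")))
  vars <- vapply(pairs, `[[`, "", "variable")
  if (anyDuplicated(vars))
    stop("population variables must be exclusively distinct within a subgroup")
  structure(list(vars = vars,
                 a = vapply(pairs, `[[`, "", "cat_a"),
                 b = vapply(pairs, `[[`, "", "cat_b")),
            class = "contrast_subgroup")
}

#' @export
length.contrast_subgroup <- function(x) length(x$vars)

#' @export
format.contrast_subgroup <- function(x, ...) {
  if (length(x) == 0L) return("(empty)")
  paste0("(", paste0(x$vars, "=", x$a, collapse = " & "), ") <-> (",
         paste0(x$vars, "=", x$b, collapse = " & "), ")")
}

#' @export
print.contrast_subgroup <- function(x, ...) {
  cat(format(x), "\n"); invisible(x)
}

#' Extend a subgroup by one contrast pair
#'
#' @param scg A \code{contrast_subgroup}.
#' @param pair A \code{contrast_pair} whose variable is not yet used in
#'   \code{scg}.
#' @return New \code{contrast_subgroup} with the pair appended; the input is
#'   unchanged.
#' @export
extend_subgroup <- function(scg, pair) {
  stopifnot(inherits(scg, "contrast_subgroup"), inherits(pair, "contrast_pair"))
  if (pair$variable %in% scg$vars)
    stop("variable '", pair$variable, "' already used in this subgroup")
  structure(list(vars = c(scg$vars, pair$variable),
                 a = c(scg$a, pair$cat_a),
                 b = c(scg$b, pair$cat_b)),
            class = "contrast_subgroup")
}

#' Remove one contrast pair from a subgroup
#'
#' @param scg A \code{contrast_subgroup} with at least 2 pairs.
#' @param pair The \code{contrast_pair} to remove (matched up to side swap).
#' @return New \code{contrast_subgroup} without that pair.
#' @export
remove_pair <- function(scg, pair) {
  stopifnot(inherits(scg, "contrast_subgroup"), inherits(pair, "contrast_pair"))
  if (length(scg) < 2L)
    stop("cannot remove a pair from a subgroup with fewer than 2 pairs")
  i <- which(scg$vars == pair$variable &
             ((scg$a == pair$cat_a & scg$b == pair$cat_b) |
              (scg$a == pair$cat_b & scg$b == pair$cat_a)))
  if (length(i) == 0L) stop("pair not present in subgroup: ", format(pair))
  keep <- setdiff(seq_along(scg$vars), i[1L])
  structure(list(vars = scg$vars[keep], a = scg$a[keep], b = scg$b[keep]),
            class = "contrast_subgroup")
}

#' Canonical key of a subgroup pair
#'
#' The key is invariant under reordering of the pairs and under a global swap
#' of the two sides, and distinct subgroups map to distinct keys. Pairs are
#' sorted by variable name; the orientation is fixed so that the first pair's
#' side-1 category precedes its side-2 category lexicographically.
#'
#' @param scg A \code{contrast_subgroup}.
#' @return Character key.
#' @export
canonical_key <- function(scg) {
  stopifnot(inherits(scg, "contrast_subgroup"))
  if (length(scg) == 0L) return("<root>")
  ord <- order(scg$vars)
  a <- scg$a[ord]; b <- scg$b[ord]; v <- scg$vars[ord]
  if (a[1L] > b[1L]) { tmp <- a; a <- b; b <- tmp }
  paste0(v, ":", a, "|", b, collapse = ";")
}

#' Parse a canonical key back into a subgroup
#' @param key A key produced by \code{\link{canonical_key}}.
#' @return A \code{contrast_subgroup}.
#' @export
subgroup_from_key <- function(key) {
  if (identical(key, "<root>")) return(contrast_subgroup())
  parts <- strsplit(strsplit(key, ";", fixed = TRUE)[[1L]], "[:|]")
  contrast_subgroup(lapply(parts, function(p) contrast_pair(p[1], p[2], p[3])))
}

#' Split the population along a subgroup definition
#'
#' Side 1 holds the records matching every side-1 category, side 2 likewise;
#' the outer group is the remainder. \code{"NA"} category cells never match.
#'
#' @param data A \code{cm_data} object.
#' @param scg A non-empty \code{contrast_subgroup} whose variables exist in
#'   \code{data}.
#' @return Object of class \code{"subgroup_split"} with integer index vectors
#'   \code{side1}, \code{side2}, \code{outer} and the data reference.
#' @export
split_population <- function(data, scg) {
  stopifnot(inherits(data, "cm_data"), inherits(scg, "contrast_subgroup"))
  if (length(scg) == 0L) stop("cannot split on an empty subgroup")
  miss <- setdiff(scg$vars, colnames(data$x))
  if (length(miss)) stop("unknown variable(s): ", paste(miss, collapse = ", "))
  m1 <- rep(TRUE, data$n); m2 <- rep(TRUE, data$n)
  for (i in seq_along(scg$vars)) {
    cats <- data$schema[[scg$vars[i]]]$categories
    col <- data$x[, scg$vars[i]]
    ca <- match(scg$a[i], cats); cb <- match(scg$b[i], cats)
    m1 <- m1 & !is.na(ca) & (col == ca)
    m2 <- m2 & !is.na(cb) & (col == cb)
  }
  side1 <- which(m1); side2 <- which(m2)
  structure(list(side1 = side1, side2 = side2,
                 outer = which(!(m1 | m2)), data = data),
            class = "subgroup_split")
}

#' @export
print.subgroup_split <- function(x, ...) {
  cat("Subgroup split: |side1| =", length(x$side1),
      "|side2| =", length(x$side2), "|outer| =", length(x$outer), "\n")
  invisible(x)
}
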
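#' Two-group allocation
#'
#' A binary assignment vector `w` over `n` units: `w[i] = 1` places unit `i`
#' in group 1 (the sampled / treated group), `w[i] = 0` in group 0.  Group
#' sizes are fixed by design.
#'
#' @param assignment Vector of 0/1 (or logical) of length `n`.
#' @param n1 Expected size of group 1; checked against `sum(assignment)`
#'   when supplied.
#' @return An object of class `"allocation"`: list with `assignment`
#'   (integer 0/1), `n1`, `n0`.
#' @examples
#' allocation(c(1, 1, 0, 0))
#' @export
allocation <- function(assignment, n1 = NULL) {
  w <- as.integer(round(as.numeric(assignment)))
  if (!all(w %in% c(0L, 1L))) stop("'assignment' must be binary (0/1)")
  s <- sum(w)
  if (!is.null(n1) && s != n1)
    stop("sum(assignment) = ", s, " does not match n1 = ", n1)
  structure(list(assignment = w, n1 = s, n0 = length(w) - s),
            class = "allocation")
}

#' @export
print.allocation <- function(x, ...) {
  cat("Two-group allocation:", length(x$assignment), "units; n1 =", x$n1,
      ", n0 =", x$n0, "\n")
  invisible(x)
}

#' Multi-group allocation
#'
#' A `g x n` binary membership matrix `W` with every column summing to 1
#' (each unit belongs to exactly one group) and row `q` summing to the fixed
#' size of group `q`.
#'
#' @param assignment Either a `g x n` binary matrix or an integer vector of
#'   group labels in `1..g` of length `n`.
#' @param group_sizes Integer vector of expected group sizes; when
#'   `assignment` is a label vector this also fixes `g`.  Checked against
#'   the realized sizes when supplied.
#' @return An object of class `"multi_allocation"`: list with `assignment`
#'   (the `g x n` matrix), `labels` (length-`n` group index vector),
#'   `group_sizes`, `g`, `n`.
#' @examples
#' multi_allocation(c(1, 1, 2, 2, 3, 3))
#' @export
multi_allocation <- function(assignment, group_sizes = NULL) {
  if (is.matrix(assignment)) {
    W <- assignment
    storage.mode(W) <- "integer"
    if (!all(W %in% c(0L, 1L))) stop("membership matrix must be binary")
    if (!all(colSums(W) == 1L)) stop("every unit must belong to exactly one group")
    labels <- apply(W, 2L, which.max)
  } else {
    labels <- as.integer(assignment)
    g <- if (!is.null(group_sizes)) length(group_sizes) else max(labels)
    if (any(labels < 1L | labels > g)) stop("group labels must lie in 1..g")
    W <- matrix(0L, g, length(labels))
    W[cbind(labels, seq_along(labels))] <- 1L
  }
  sizes <- as.integer(rowSums(W))
  if (!is.null(group_sizes)) {
    if (length(group_sizes) != nrow(W) || !all(sizes == group_sizes))
      stop("realized group sizes (", paste(sizes, collapse = ", "),
           ") do not match 'group_sizes'")
  }
  if (any(sizes == 0L)) stop("empty group in allocation")
  structure(list(assignment = W, labels = as.integer(labels),
                 group_sizes = sizes, g = nrow(W), n = ncol(W)),
            class = "multi_allocation")
}

#' @export
print.multi_allocation <- function(x, ...) {
  cat("Multi-group allocation:", x$n, "units in", x$g, "groups of sizes (",
      paste(x$group_sizes, collapse = ", "), ")\n")
  invisible(x)
}

# internal: group labels for either allocation flavour.
# two-group convention: group 1 -> label 1, group 0 -> label 2, so that the
# first group is always the sampled/treated one.
alloc_labels <- function(alloc) {
  if (inherits(alloc, "allocation")) return(2L - alloc$assignment)
  if (inherits(alloc, "multi_allocation")) return(alloc$labels)
  stop("expected an 'allocation' or 'multi_allocation'")
}

alloc_sizes <- function(alloc) {
  if (inherits(alloc, "allocation")) return(c(alloc$n1, alloc$n0))
  alloc$group_sizes
}
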
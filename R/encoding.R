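#' Enumerate pairwise rank features from neighborhoods
#'
#' For every measured protein `i` and every measured protein `j` whose base
#' node lies in the network neighborhood of `i`'s base node, one unordered
#' feature pair `{i, j}` is produced. Phospho-forms inherit the neighborhood
#' of their unphosphorylated base node and are additionally paired with the
#' base protein itself and with any other measured forms of the same base
#' node. Each unordered pair is stored once, in lexicographic orientation,
#' and the output is sorted for determinism.
#'
#' @param neighborhoods named list of `neighborhood` objects keyed by base
#'   node (see [sample_neighborhoods()])
#' @param measured_ids character vector of measured protein identifiers
#'   (columns of the expression matrix)
#' @param mapping optional mapping table (see [read_protein_mapping()]);
#'   without it the phospho-suffix heuristic of [map_measured()] is applied
#' @param pair_phospho_siblings include pairs between two measured forms of
#'   the same base protein (default `TRUE`)
#' @return data.frame with columns `left`, `right` (measured ids,
#'   `left < right`) and `feature` (`"left|right"`)
#' @export
build_feature_pairs <- function(neighborhoods, measured_ids, mapping = NULL,
                                pair_phospho_siblings = TRUE) {
  res <- resolve_mapping(measured_ids, mapping)
  base <- res$base_node
  names(base) <- res$measured_id

  members <- lapply(neighborhoods, `[[`, "members")
  left <- character(0); right <- character(0)
  for (i in measured_ids) {
    bi <- base[[i]]
    nb <- members[[bi]]
    partners <- if (is.null(nb)) character(0) else measured_ids[base %in% nb]
    if (pair_phospho_siblings) {
      partners <- c(partners, measured_ids[base == bi])
    }
    partners <- setdiff(partners, i)
    if (length(partners)) {
      left <- c(left, rep(i, length(partners)))
      right <- c(right, partners)
    }
  }
  none <- measured_ids[!measured_ids %in% c(left, right)]
  if (length(none)) {
    message(sprintf("%d measured protein(s) contribute no pairs: %s",
                    length(none), paste(utils::head(none, 5L), collapse = ", ")))
  }
  if (!length(left)) {
    return(data.frame(left = character(0), right = character(0),
                      feature = character(0), stringsAsFactors = FALSE))
  }
  a <- pmin(left, right)
  b <- pmax(left, right)
  key <- paste(a, b, sep = "|")
  keep <- !duplicated(key)
  out <- data.frame(left = a[keep], right = b[keep], feature = key[keep],
                    stringsAsFactors = FALSE)
  out[order(out$feature), , drop = FALSE]
}

check_expression <- function(expr, pairs) {
  expr <- as.matrix(expr)
  if (!is.numeric(expr)) stop("expression matrix must be numeric")
  if (anyNA(expr)) stop("expression matrix contains missing values; impute upstream")
  if (anyDuplicated(colnames(expr))) stop("duplicate protein columns in expression matrix")
  if (anyDuplicated(rownames(expr))) stop("duplicate patient rows in expression matrix")
  need <- unique(c(pairs$left, pairs$right))
  miss <- setdiff(need, colnames(expr))
  if (length(miss)) {
    stop(sprintf("expression matrix lacks column(s): %s",
                 paste(miss, collapse = ", ")))
  }
  expr
}

#' Binary pairwise rank encoding
#'
#' For patient `k` and feature pair `(i, j)` the entry is `+1` when
#' `x_i^(k) > x_j^(k)` and `-1` otherwise (ties fall in the "otherwise"
#' branch). Because only the ordering of the two values matters, the encoding
#' is invariant to any strictly increasing transform of a patient's
#' expression profile.
#'
#' @param expr numeric matrix, patients in rows, measured proteins in
#'   columns (row and column names required)
#' @param pairs data.frame from [build_feature_pairs()]
#' @param tie_value value assigned when `x_i == x_j` (default `-1`)
#' @return numeric matrix patients x pairs with entries in `{-1, 1}`;
#'   columns named `"i|j"`; attribute `variant = "binary"`
#' @export
encode_binary <- function(expr, pairs, tie_value = -1) {
  expr <- check_expression(expr, pairs)
  L <- expr[, pairs$left, drop = FALSE]
  R <- expr[, pairs$right, drop = FALSE]
  out <- matrix(-1, nrow(expr), nrow(pairs),
                dimnames = list(rownames(expr), pairs$feature))
  out[L > R] <- 1
  if (tie_value != -1) out[L == R] <- tie_value
  attr(out, "variant") <- "binary"
  out
}

#' Ternary pairwise rank encoding
#'
#' As [encode_binary()], but an entry is set to 0 when the two expression
#' values differ by less than `rel_threshold` times the magnitude of the
#' compared neighbor (the pair's right protein): `|x_i - x_j| <
#' rel_threshold * |x_j|`. The absolute value in the denominator makes the
#' band well defined for normalized expression values that can be negative.
#'
#' @inheritParams encode_binary
#' @param rel_threshold relative difference below which the pair is called
#'   indistinguishable (default 0.10)
#' @return numeric matrix with entries in `{-1, 0, 1}`; attribute
#'   `variant = "ternary"`
#' @export
encode_ternary <- function(expr, pairs, rel_threshold = 0.10) {
  if (!is.numeric(rel_threshold) || rel_threshold < 0) {
    stop("`rel_threshold` must be >= 0")
  }
  expr <- check_expression(expr, pairs)
  L <- expr[, pairs$left, drop = FALSE]
  R <- expr[, pairs$right, drop = FALSE]
  out <- matrix(-1, nrow(expr), nrow(pairs),
                dimnames = list(rownames(expr), pairs$feature))
  out[L > R] <- 1
  out[abs(L - R) < rel_threshold * abs(R)] <- 0
  attr(out, "variant") <- "ternary"
  attr(out, "rel_threshold") <- rel_threshold
  out
}

#' Network propagation of expression values
#'
#' Insulated-diffusion baseline: per patient, expression values are smoothed
#' over the interaction network by iterating
#' `F <- alpha * F %*% S + (1 - alpha) * F0` with `S` the symmetrically
#' degree-normalized adjacency (`D^{-1/2} A D^{-1/2}`) of the subgraph
#' induced by the measured nodes, until the largest entry change falls below
#' `tol`. Columns whose identifier is not a network node (or that are
#' isolated within the induced subgraph) keep their observed values.
#'
#' @param expr numeric matrix, patients x measured proteins (column names
#'   are network node ids)
#' @param net a `ppi_network`
#' @param alpha diffusion strength in (0, 1); default 0.5
#' @param tol convergence tolerance on the maximum absolute change
#' @param max_iter iteration cap
#' @return matrix of the same shape as `expr` with diffused values
#' @export
propagate_expression <- function(expr, net, alpha = 0.5, tol = 1e-6,
                                 max_iter = 1000L) {
  stopifnot(inherits(net, "ppi_network"))
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must lie strictly between 0 and 1")
  }
  expr <- as.matrix(expr)
  if (anyNA(expr)) stop("expression matrix contains missing values")
  incols <- colnames(expr)[colnames(expr) %in% net$nodes]
  outcols <- setdiff(colnames(expr), incols)
  if (length(outcols)) {
    message(sprintf("%d column(s) are not network nodes and pass through unchanged",
                    length(outcols)))
  }
  if (length(incols) < 2L) return(expr)

  e <- net$edges
  keep <- e$node_a %in% incols & e$node_b %in% incols
  A <- matrix(0, length(incols), length(incols),
              dimnames = list(incols, incols))
  if (any(keep)) {
    ia <- match(e$node_a[keep], incols)
    ib <- match(e$node_b[keep], incols)
    A[cbind(ia, ib)] <- 1
    A[cbind(ib, ia)] <- 1
  }
  deg <- rowSums(A)
  dinv <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  S <- A * (dinv %o% dinv)

  F0 <- expr[, incols, drop = FALSE]
  Fc <- F0
  for (it in seq_len(max_iter)) {
    Fn <- alpha * (Fc %*% S) + (1 - alpha) * F0
    delta <- max(abs(Fn - Fc))
    Fc <- Fn
    if (delta < tol) {
      expr[, incols] <- Fc
      return(expr)
    }
  }
  stop(sprintf("propagation did not converge in %d iterations (residual %.3g)",
               max_iter, delta))
}
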
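#' Read a rooted phylogeny from Newick
#'
#' Parses a Newick string or file, requires branch lengths, and resolves
#' polytomies into arbitrary bifurcations with zero-length internal edges
#' (logged via a message). Underscores in tip labels are preserved.
#'
#' @param source a Newick string (recognized by a leading parenthesis) or a
#'   path to a Newick file.
#' @return an \code{ape::phylo} tree, rooted and strictly bifurcating.
#' @export
read_newick <- function(source) {
  txt <- if (grepl("^\\s*\\(", source)) source
         else paste(readLines(source, warn = FALSE), collapse = "")
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) stop("Newick parse error: ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("Newick parse error: no tree found")
  if (is.null(tree$edge.length))
    stop("Newick parse error: branch lengths are required (tree '",
         substr(txt, 1, 30), "...' has none)")
  if (anyNA(tree$edge.length))
    stop("Newick parse error: a branch is missing its length")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (!ape::is.binary(tree) || !ape::is.rooted(tree)) {
    message("polytomies resolved into zero-length bifurcations")
    tree <- ape::multi2di(tree, random = FALSE)
  }
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  tree
}

#' Phylogenetic covariance matrix of a tree
#'
#' C[i, j] is the shared root-to-MRCA path length of tips i and j (the
#' expected Brownian covariance), C[i, i] the depth of tip i.
#'
#' @param tree an \code{ape::phylo} tree.
#' @return symmetric positive-semidefinite species x species matrix in
#'   branch-length units.
#' @export
phylo_vcv <- function(tree) ape::vcv(tree)

#' Felsenstein's phylogenetically independent contrasts
#'
#' Post-order pruning: at each internal node with daughter values x1, x2 on
#' (extended) branches b1, b2 the standardized contrast is
#' (x1 - x2) / sqrt(b1 + b2), the node value is the weighted average
#' (x1/b1 + x2/b2) / (1/b1 + 1/b2), and the node's parent branch is
#' extended by b1 b2 / (b1 + b2). A bifurcating tree with n tips yields
#' n - 1 contrasts, each in trait units per sqrt(branch length).
#'
#' @param tree a rooted, strictly bifurcating \code{ape::phylo} tree with
#'   branch lengths (resolve polytomies first, e.g. via
#'   \code{\link{read_newick}}).
#' @param x named numeric vector of tip values covering every tip label.
#' @return object of class \code{contrast_set}: list with \code{contrasts}
#'   and \code{expected_variances} (= b1 + b2), both named by internal node
#'   number, and \code{n_tips}.
#' @export
compute_pics <- function(tree, x) {
  if (!ape::is.binary(tree))
    stop("tree must be strictly bifurcating; resolve polytomies first")
  ntip <- length(tree$tip.label)
  if (!all(tree$tip.label %in% names(x)))
    stop("missing tip values for: ",
         paste(setdiff(tree$tip.label, names(x)), collapse = ", "))
  x <- x[tree$tip.label]
  if (anyNA(x)) stop("tip values contain NA")

  po <- ape::reorder.phylo(tree, "postorder")
  nnode <- tree$Nnode
  val <- c(as.numeric(x), rep(NA_real_, nnode))
  blen <- numeric(ntip + nnode)       # (extended) branch above each node
  blen[po$edge[, 2]] <- po$edge.length
  contrasts <- variances <- stats::setNames(rep(NA_real_, nnode),
                                            ntip + seq_len(nnode))
  # process each internal node once both daughter edges have been visited
  rows_by_node <- split(seq_len(nrow(po$edge)), po$edge[, 1])
  node_order <- names(rows_by_node)[order(vapply(rows_by_node, max, 1L))]
  for (nd in node_order) {
    node <- as.integer(nd)
    rows <- rows_by_node[[nd]]
    c1 <- po$edge[rows[1], 2]; c2 <- po$edge[rows[2], 2]
    b1 <- blen[c1]; b2 <- blen[c2]
    if (b1 + b2 <= 0)
      stop("zero-variance contrast at node ", node,
           ": both daughter branches have length 0")
    key <- as.character(node)
    contrasts[key] <- (val[c1] - val[c2]) / sqrt(b1 + b2)
    variances[key] <- b1 + b2
    val[node] <- (val[c1] / b1 + val[c2] / b2) / (1 / b1 + 1 / b2)
    blen[node] <- blen[node] + b1 * b2 / (b1 + b2)
  }
  structure(list(contrasts = contrasts, expected_variances = variances,
                 n_tips = ntip), class = "contrast_set")
}

#' @export
print.contrast_set <- function(x, ...) {
  cat(sprintf("Independent contrasts: %d contrasts from %d tips\n",
              length(x$contrasts), x$n_tips))
  print(utils::head(cbind(contrast = x$contrasts,
                          expected_variance = x$expected_variances), 6L))
  invisible(x)
}

#' Phylogenetically corrected principal components analysis
#'
#' Eigenanalysis of the evolutionary (GLS, tree-corrected) trait
#' correlation matrix. With tip matrix X and phylogenetic covariance C, the
#' phylogenetic (GLS) mean is a = (1' C^-1 1)^-1 1' C^-1 X and the
#' evolutionary covariance R = (X - 1a)' C^-1 (X - 1a) / (n - 1);
#' correlation mode standardizes R to unit diagonal and standardizes the
#' centered data columns accordingly before projecting them on the
#' eigenvectors. The resulting axes are evolutionarily independent.
#'
#' Species with any missing trait are dropped (complete-case, logged) and
#' the tree is pruned to the retained species.
#'
#' @param tree an \code{ape::phylo} tree whose tip labels cover the table's
#'   species (exact, case-sensitive matching).
#' @param traits a \code{\link{trait_table}} or species x trait matrix.
#' @param mode \code{"correlation"} (default; eigenvalues sum to the number
#'   of traits) or \code{"covariance"}.
#' @return object of class \code{phylo_pca}: eigenvalues (descending),
#'   loadings (orthonormal eigenvectors), scores, evolutionary correlation
#'   matrix, \code{integration_index}, \code{dimensionality}, \code{N}
#'   (traits), \code{n} (species), \code{mode}, \code{species}.
#' @export
phylo_pca <- function(tree, traits, mode = c("correlation", "covariance")) {
  mode <- match.arg(mode)
  if (inherits(traits, "trait_table")) traits <- complete_species(traits)
  X <- as.matrix(traits)
  keep <- stats::complete.cases(X)
  if (any(!keep)) {
    message(sum(!keep), " species dropped (incomplete traits)")
    X <- X[keep, , drop = FALSE]
  }
  missing_sp <- setdiff(rownames(X), tree$tip.label)
  if (length(missing_sp) > 0)
    stop("species absent from the tree: ",
         paste(missing_sp, collapse = ", "))
  if (length(setdiff(tree$tip.label, rownames(X))) > 0)
    tree <- ape::drop.tip(tree, setdiff(tree$tip.label, rownames(X)))
  n <- nrow(X); N <- ncol(X)
  if (n <= N)
    stop("rank deficiency: need more species (", n, ") than traits (",
         N, ")")
  C <- ape::vcv(tree)
  X <- X[rownames(C), , drop = FALSE]
  Cinv <- tryCatch(solve(C), error = function(e)
    stop("singular phylogenetic covariance; check for zero-length ",
         "tip branches"))
  one <- rep(1, n)
  a <- drop(crossprod(one, Cinv %*% X)) / drop(crossprod(one, Cinv %*% one))
  Xc <- sweep(X, 2, a)
  R <- crossprod(Xc, Cinv %*% Xc) / (n - 1)
  if (mode == "correlation") {
    s <- sqrt(diag(R))
    if (any(s == 0)) stop("zero evolutionary variance for trait(s): ",
                          paste(colnames(X)[s == 0], collapse = ", "))
    Rm <- R / tcrossprod(s)
    Xs <- sweep(Xc, 2, s, `/`)
  } else {
    Rm <- R
    Xs <- Xc
  }
  e <- eigen(Rm, symmetric = TRUE)
  if (min(e$values) < -1e-10 * max(1, max(abs(e$values))))
    stop("evolutionary correlation matrix has a substantially negative ",
         "eigenvalue; input is inconsistent")
  lambda <- pmax(e$values, 0)
  loadings <- e$vectors
  dimnames(loadings) <- list(colnames(X), paste0("PC", seq_len(N)))
  scores <- Xs %*% loadings
  idx <- if (mode == "correlation") integration_index(lambda) else NA_real_
  dim_k <- kaiser_dimensionality(lambda)
  structure(list(eigenvalues = lambda, loadings = loadings,
                 scores = scores, evolutionary_correlation = Rm,
                 evolutionary_covariance = R,
                 integration_index = idx, dimensionality = dim_k,
                 N = N, n = n, mode = mode, species = rownames(X)),
            class = "phylo_pca")
}

#' @export
print.phylo_pca <- function(x, ...) {
  cat(sprintf("Phylogenetic PCA (%s mode): %d species, %d traits\n",
              x$mode, x$n, x$N))
  cat("Eigenvalues:", paste(sprintf("%.3f", x$eigenvalues),
                            collapse = ", "), "\n")
  if (!is.na(x$integration_index))
    cat(sprintf("Integration index Var(lambda): %.3f\n",
                x$integration_index))
  cat("Kaiser dimensionality:", x$dimensionality, "\n")
  invisible(x)
}

#' Eigenvalue-variance phenotypic integration index
#'
#' Var(lambda) = sum((lambda_i - 1)^2) / N for the eigenvalues of a
#' correlation-matrix eigenanalysis (which average 1). The index is 0 when
#' traits are uncorrelated and N - 1 when a single axis carries all
#' variation.
#'
#' @param eigenvalues numeric vector of correlation-matrix eigenvalues.
#' @return the index (dimensionless, >= 0).
#' @export
integration_index <- function(eigenvalues) {
  N <- length(eigenvalues)
  if (abs(sum(eigenvalues) - N) > 1e-6)
    warning("eigenvalues do not sum to their count; the index assumes a ",
            "correlation-matrix eigenanalysis")
  sum((eigenvalues - 1)^2) / N
}

#' Kaiser-rule dimensionality
#'
#' The number of eigenvalues strictly greater than 1, 1 being the average
#' eigenvalue of a correlation matrix.
#'
#' @param eigenvalues numeric vector of correlation-matrix eigenvalues.
#' @return integer count (>= 0).
#' @export
kaiser_dimensionality <- function(eigenvalues) {
  if (length(eigenvalues) > 0 && all(abs(eigenvalues - 1) < 1e-12))
    warning("degenerate spectrum: all eigenvalues equal 1")
  sum(eigenvalues > 1)
}
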
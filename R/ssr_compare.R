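#' Build a species-by-motif presence/absence matrix
#'
#' Encodes, for every species, which exact SSR motif strings occur at least
#' once in its genome. The motif universe is the union over species, so
#' every column is present in at least one species.
#'
#' @param loci a tibble with at least `species` and `motif` columns — e.g.
#'   row-bound [detect_ssrs()] results with a `species` column added, or a
#'   long-format motif table.
#' @return a `motif_matrix`: a tibble whose first column is `species` and
#'   whose remaining columns are 0/1 motif indicators.
#' @export
build_motif_matrix <- function(loci) {
  stopifnot(is.data.frame(loci), all(c("species", "motif") %in% names(loci)))
  species <- unique(loci$species)
  if (length(species) < 2L) {
    abort("A motif matrix needs at least 2 species.")
  }
  motifs <- sort(unique(loci$motif))
  cells <- matrix(0L, nrow = length(species), ncol = length(motifs),
                  dimnames = list(species, motifs))
  present <- distinct(loci, .data$species, .data$motif)
  cells[cbind(match(present$species, species),
              match(present$motif, motifs))] <- 1L
  out <- as_tibble(cells)
  out <- dplyr::bind_cols(tibble(species = species), out)
  class(out) <- c("motif_matrix", class(out))
  out
}

motif_cells <- function(matrix) {
  stopifnot(is.data.frame(matrix), names(matrix)[1] == "species")
  m <- as.matrix(matrix[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- matrix$species
  m
}

#' Motif informativeness (balance) index
#'
#' For each motif column, `min(n_present, n_absent) / n_species` — maximal
#' (0.5) when a motif splits the species set in half, 0 when it is fixed
#' present or absent. This is the index used to rank phylogenetically
#' informative cpSSR motifs.
#'
#' @param matrix a [build_motif_matrix()] result.
#' @param motif optional motif label(s) to restrict to; unknown motifs are
#'   an error.
#' @return a tibble sorted by decreasing index: `motif`, `present_in`,
#'   `absent_in`, `balance_index`.
#' @examples
#' m <- tibble::tibble(species = paste0("sp", 1:10),
#'                     TTA = rep(1:0, each = 5))
#' class(m) <- c("motif_matrix", class(m))
#' balance_index(m)  # TTA: 5 present, 5 absent, index 0.5
#' @export
balance_index <- function(matrix, motif = NULL) {
  cells <- motif_cells(matrix)
  if (!is.null(motif)) {
    missing <- setdiff(motif, colnames(cells))
    if (length(missing)) {
      abort(paste0("Unknown motif(s): ", paste(missing, collapse = ", ")))
    }
    cells <- cells[, motif, drop = FALSE]
  }
  n <- nrow(cells)
  present <- colSums(cells)
  out <- tibble(
    motif = colnames(cells),
    present_in = as.integer(present),
    absent_in = as.integer(n - present),
    balance_index = unname(pmin(present, n - present)) / n
  )
  arrange(out, dplyr::desc(.data$balance_index), .data$motif)
}

#' Sørensen dissimilarity between species motif repertoires
#'
#' `d(i, j) = 1 - 2|P_i ∩ P_j| / (|P_i| + |P_j|)` over motif presence
#' sets — 0 for identical repertoires, 1 for disjoint ones.
#'
#' @param matrix a [build_motif_matrix()] result; every species must carry
#'   at least one motif.
#' @return a [stats::dist] object labelled by species.
#' @export
sorensen_dissimilarity <- function(matrix) {
  cells <- motif_cells(matrix)
  sizes <- rowSums(cells)
  if (any(sizes == 0)) {
    abort(paste0("Species with empty motif repertoire: ",
                 paste(rownames(cells)[sizes == 0], collapse = ", ")))
  }
  inter <- cells %*% t(cells)
  d <- 1 - 2 * inter / outer(sizes, sizes, "+")
  diag(d) <- 0
  stats::as.dist(d)
}

#' Ward.D2 hierarchical clustering of a dissimilarity matrix
#'
#' Agglomerative clustering under Ward's minimum-variance criterion with
#' the Lance-Williams update applied to squared dissimilarities; merge
#' heights are reported on the unsquared scale.
#'
#' @param d a [stats::dist] object or symmetric numeric matrix with
#'   labels; no missing values.
#' @return an [stats::hclust] tree. Export with [write_newick()].
#' @export
ward_cluster <- function(d) {
  if (is.matrix(d)) d <- stats::as.dist(d)
  stopifnot(inherits(d, "dist"))
  if (anyNA(d) || any(!is.finite(d))) abort("Distances must be finite.")
  if (attr(d, "Size") < 2L) abort("Need at least 2 items to cluster.")
  hclust(d, method = "ward.D2")
}

#' Write a dendrogram as Newick
#'
#' @param tree an [stats::hclust] tree (e.g. from [ward_cluster()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "hclust"))
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}

#' Mantel permutation test between two distance matrices
#'
#' Pearson correlation over the upper-triangle entries, with a one-sided
#' (greater) permutation p-value obtained by jointly permuting rows and
#' columns of `d2`: `p = (1 + #\{r_perm >= r_obs\}) / (1 + n_permutations)`.
#'
#' @param d1,d2 [stats::dist] objects with identical labels in identical
#'   order (labels are required on both).
#' @param n_permutations number of permutations (default 999).
#' @param seed integer seed; required, so runs are reproducible.
#' @return an object of class `mantel_result` with elements `r_observed`,
#'   `p_value`, `n_permutations`, `seed`, `perm` (the permuted statistics).
#'   Use [generics::tidy()] for a one-row tibble.
#' @export
mantel_test <- function(d1, d2, n_permutations = 999, seed) {
  stopifnot(inherits(d1, "dist"), inherits(d2, "dist"))
  if (missing(seed)) abort("`seed` is required for the Mantel permutation test.")
  l1 <- attr(d1, "Labels"); l2 <- attr(d2, "Labels")
  if (is.null(l1) || is.null(l2) || !identical(l1, l2)) {
    abort("Distance matrices must carry identical labels in identical order.")
  }
  if (attr(d1, "Size") < 4L) abort("Mantel test needs at least 4 items.")
  if (stats::sd(as.vector(d1)) == 0 || stats::sd(as.vector(d2)) == 0) {
    abort("Zero variance in a distance matrix; Mantel r undefined.")
  }
  set.seed(seed)
  res <- vegan::mantel(d1, d2, method = "pearson",
                       permutations = n_permutations)
  structure(
    list(r_observed = unname(res$statistic),
         p_value = unname(res$signif),
         n_permutations = n_permutations,
         seed = seed,
         perm = res$perm),
    class = "mantel_result"
  )
}

#' @export
print.mantel_result <- function(x, ...) {
  cat("Mantel test: r =", format(x$r_observed, digits = 4),
      ", p =", format(x$p_value, digits = 4),
      paste0("(", x$n_permutations, " permutations, seed ", x$seed, ")\n"))
  invisible(x)
}

#' Correlation between total SSR count and SSR density
#'
#' Pearson correlation of per-species total SSR count against density
#' (count per kb of genome), the cross-species abundance trend statistic.
#'
#' @param per_species a tibble with columns `n_ssrs` and `genome_length`
#'   (bp), one row per species.
#' @return a one-row tibble: `r`, `n_species`.
#' @export
count_density_correlation <- function(per_species) {
  stopifnot(is.data.frame(per_species),
            all(c("n_ssrs", "genome_length") %in% names(per_species)))
  n <- nrow(per_species)
  if (n < 2L) abort("Need at least 2 species.")
  density <- per_species$n_ssrs / per_species$genome_length * 1000
  if (stats::sd(per_species$n_ssrs) == 0 || stats::sd(density) == 0) {
    abort("Constant counts or densities; correlation undefined.")
  }
  tibble(r = cor(per_species$n_ssrs, density), n_species = n)
}
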
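alignment_matrix <- function(alignment) {
  stopifnot(is.data.frame(alignment),
            all(c("taxon", "sequence") %in% names(alignment)))
  if (anyDuplicated(alignment$taxon)) abort("Duplicate taxon labels.")
  lens <- nchar(alignment$sequence)
  if (length(unique(lens)) != 1L) abort("Alignment rows differ in length.")
  m <- do.call(rbind, strsplit(alignment$sequence, "", fixed = TRUE))
  rownames(m) <- alignment$taxon
  m
}

#' Nucleotide diversity (Pi) of an alignment
#'
#' The mean pairwise difference proportion: for every unordered pair of
#' rows, the number of differing sites divided by the number of compared
#' sites, averaged over all `n(n-1)/2` pairs. Under complete deletion (the
#' default) a column containing any gap or `N` is excluded for all pairs,
#' so every pair is compared over the same columns; under pairwise
#' deletion each pair uses the columns where both of its rows are
#' ungapped A/C/G/T.
#'
#' @param alignment a tibble with `taxon` and `sequence` columns (equal
#'   lengths, alphabet `{A,C,G,T,N,-}`), e.g. from
#'   [read_alignment_fasta()]; at least 2 rows.
#' @param deletion `"complete"` (default) or `"pairwise"`.
#' @return Pi, a non-negative scalar.
#' @examples
#' aln <- tibble::tibble(taxon = c("a", "b"),
#'                       sequence = c(strrep("A", 100),
#'                                    paste0(strrep("A", 99), "G")))
#' nucleotide_diversity(aln)  # 0.01
#' @export
nucleotide_diversity <- function(alignment,
                                 deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  m <- alignment_matrix(alignment)
  if (nrow(m) < 2L) abort("Pi needs at least 2 sequences.")
  valid <- m %in% c("A", "C", "G", "T")
  dim(valid) <- dim(m)
  pairs <- utils::combn(nrow(m), 2L)
  if (deletion == "complete") {
    cols <- which(colSums(valid) == nrow(m))
    if (length(cols) == 0L) {
      abort("Pi undefined: no column is free of gaps and N in all rows.")
    }
    d <- apply(pairs, 2L, function(p) {
      sum(m[p[1], cols] != m[p[2], cols]) / length(cols)
    })
  } else {
    d <- apply(pairs, 2L, function(p) {
      ok <- valid[p[1], ] & valid[p[2], ]
      if (!any(ok)) abort("Pi undefined: a pair shares no comparable column.")
      sum(m[p[1], ok] != m[p[2], ok]) / sum(ok)
    })
  }
  mean(d)
}

#' Sliding-window nucleotide diversity
#'
#' Pi in full windows tiled from column 1: windows start at
#' `1, 1 + step, ...` while `start + window - 1 <= length`; trailing
#' partial windows are dropped. Each window's Pi uses complete deletion
#' within the window; a window with no valid site gets `NA`.
#'
#' @param alignment see [nucleotide_diversity()].
#' @param window window length in alignment columns (default 600).
#' @param step step size in columns (default 200).
#' @return a tibble of class `pi_windows`: `start`, `end`, `midpoint`,
#'   `valid_sites`, `pi`.
#' @export
sliding_pi <- function(alignment, window = 600, step = 200) {
  if (window <= 0 || step <= 0) abort("`window` and `step` must be positive.")
  m <- alignment_matrix(alignment)
  L <- ncol(m)
  if (L < window) abort("Alignment shorter than one window.")
  starts <- seq(1L, L - window + 1L, by = step)
  valid <- m %in% c("A", "C", "G", "T")
  dim(valid) <- dim(m)
  all_valid <- colSums(valid) == nrow(m)
  pairs <- utils::combn(nrow(m), 2L)
  res <- map(starts, function(s) {
    cols <- which(all_valid[s:(s + window - 1L)]) + s - 1L
    if (length(cols) == 0L) return(list(valid_sites = 0L, pi = NA_real_))
    d <- apply(pairs, 2L, function(p) {
      sum(m[p[1], cols] != m[p[2], cols]) / length(cols)
    })
    list(valid_sites = length(cols), pi = mean(d))
  })
  out <- tibble(
    start = as.integer(starts),
    end = as.integer(starts + window - 1L),
    midpoint = (starts + starts + window - 1) / 2,
    valid_sites = map_int(res, "valid_sites"),
    pi = map_dbl(res, "pi")
  )
  class(out) <- c("pi_windows", class(out))
  out
}

#' Conservation category of a Pi value
#'
#' Four half-open classes: `pi < 0.012` highly conserved, `< 0.024`
#' conserved, `< 0.038` variable, otherwise highly variable.
#'
#' @param pi numeric vector of non-negative Pi values.
#' @return a factor with levels `highly_conserved`, `conserved`,
#'   `variable`, `highly_variable`.
#' @examples
#' classify_diversity(c(0.009, 0.034, 0.057))
#' @export
classify_diversity <- function(pi) {
  if (any(!is.finite(pi)) || any(pi < 0)) {
    abort("Pi values must be finite and non-negative.")
  }
  cut(pi, breaks = c(-Inf, 0.012, 0.024, 0.038, Inf), right = FALSE,
      labels = c("highly_conserved", "conserved", "variable",
                 "highly_variable"))
}

#' Per-gene nucleotide diversity
#'
#' Pi over each gene's alignment columns, given a gene-to-column map; the
#' alignment is consumed as supplied, never re-aligned.
#'
#' @param alignment see [nucleotide_diversity()].
#' @param gene_map a tibble: `gene_id`, `start_col`, `end_col`, `region`
#'   (one of `LSC`, `SSC`, `IR`).
#' @return a tibble: `gene_id`, `region`, `pi`, `category`.
#' @export
gene_diversity <- function(alignment, gene_map) {
  stopifnot(all(c("gene_id", "start_col", "end_col", "region") %in%
                  names(gene_map)))
  L <- nchar(alignment$sequence[1])
  if (any(gene_map$start_col < 1 | gene_map$end_col > L |
            gene_map$start_col > gene_map$end_col)) {
    abort("Gene column interval outside the alignment.")
  }
  pis <- map_dbl(seq_len(nrow(gene_map)), function(i) {
    sub <- mutate(alignment,
                  sequence = substr(.data$sequence,
                                    gene_map$start_col[i],
                                    gene_map$end_col[i]))
    nucleotide_diversity(sub)
  })
  tibble(gene_id = gene_map$gene_id, region = gene_map$region,
         pi = pis, category = classify_diversity(pis))
}

#' Regional variability summary
#'
#' Cross-tabulates gene conservation categories by region, with each
#' category's share of all genes, and the headline share of genes at
#' `Pi >= 0.024` (variable or highly variable) overall and per region,
#' half-up rounded at 1 decimal.
#'
#' @param gene_div a [gene_diversity()] tibble (columns `gene_id`,
#'   `region`, `pi`, `category`).
#' @return a list of class `regional_variability` with `counts` (category
#'   x region counts plus `total` and `pct_of_total`) and
#'   `variable_share` (`region`, `n_variable`, `n_genes`, `pct`; the
#'   `overall` row first).
#' @export
regional_variability_summary <- function(gene_div) {
  stopifnot(all(c("region", "pi", "category") %in% names(gene_div)))
  if (nrow(gene_div) == 0L) abort("No genes supplied.")
  cats <- c("highly_variable", "variable", "conserved", "highly_conserved")
  regions <- c("LSC", "SSC", "IR")
  tab <- table(factor(gene_div$category, levels = cats),
               factor(gene_div$region, levels = regions))
  counts <- as_tibble(as.data.frame.matrix(tab))
  counts <- dplyr::bind_cols(tibble(category = cats), counts)
  counts$total <- as.integer(rowSums(tab))
  counts$pct_of_total <- round_half_up(100 * counts$total / nrow(gene_div), 1)
  share_of <- function(df) {
    n_var <- sum(df$pi >= 0.024)
    tibble(n_variable = n_var, n_genes = nrow(df),
           pct = round_half_up(100 * n_var / nrow(df), 1))
  }
  per_region <- bind_rows(lapply(regions, function(r) {
    df <- gene_div[gene_div$region == r, , drop = FALSE]
    if (nrow(df) == 0L) {
      return(tibble(region = r, n_variable = 0L, n_genes = 0L,
                    pct = NA_real_))
    }
    dplyr::bind_cols(tibble(region = r), share_of(df))
  }))
  overall <- dplyr::bind_cols(tibble(region = "overall"),
                              share_of(gene_div))
  structure(
    list(counts = counts,
         variable_share = bind_rows(overall, per_region)),
    class = "regional_variability"
  )
}

#' @export
print.regional_variability <- function(x, ...) {
  cat("Gene conservation categories by region:\n")
  print(as.data.frame(x$counts), row.names = FALSE)
  cat("\nShare of genes with Pi >= 0.024:\n")
  print(as.data.frame(x$variable_share), row.names = FALSE)
  invisible(x)
}
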
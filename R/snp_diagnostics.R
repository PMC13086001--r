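PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

#' Classify a substitution as transition or transversion
#'
#' Purine-to-purine (A/G) or pyrimidine-to-pyrimidine (C/T) changes are
#' transitions; cross-class changes are transversions. Of the 12 ordered
#' base pairs, 4 are transitions and 8 transversions.
#'
#' @param ref_base,alt_base single bases in `{A,C,G,T}` (vectorised);
#'   identical bases or gap/N input are an error.
#' @return character vector: `"transition"` or `"transversion"`.
#' @examples
#' classify_substitution("A", "G")  # transition
#' classify_substitution("G", "T")  # transversion
#' @export
classify_substitution <- function(ref_base, alt_base) {
  if (any(!ref_base %in% c(PURINES, PYRIMIDINES)) ||
      any(!alt_base %in% c(PURINES, PYRIMIDINES))) {
    abort("Bases must be one of A, C, G, T.")
  }
  if (any(ref_base == alt_base)) {
    abort("Identical bases do not constitute a substitution.")
  }
  ifelse((ref_base %in% PURINES) == (alt_base %in% PURINES),
         "transition", "transversion")
}

#' A/T gain-loss effect of a substitution
#'
#' Labels how a reference-to-derived change moves A/T content:
#' `loses_A`/`loses_T` when the reference base is A or T, `gains_A`/
#' `gains_T` when the derived base is. A C<->G change carries no label.
#'
#' @param ref_base,alt_base single bases in `{A,C,G,T}` (vectorised);
#'   identical bases are an error.
#' @return character vector of comma-joined labels (`""` when empty),
#'   e.g. `"loses_A,gains_T"` for A->T.
#' @export
ta_effect <- function(ref_base, alt_base) {
  if (any(!ref_base %in% c(PURINES, PYRIMIDINES)) ||
      any(!alt_base %in% c(PURINES, PYRIMIDINES))) {
    abort("Bases must be one of A, C, G, T.")
  }
  if (any(ref_base == alt_base)) {
    abort("Identical bases do not constitute a substitution.")
  }
  mapply(function(r, a) {
    labels <- character()
    if (r %in% c("A", "T")) labels <- c(labels, paste0("loses_", r))
    if (a %in% c("A", "T")) labels <- c(labels, paste0("gains_", a))
    paste(labels, collapse = ",")
  }, ref_base, alt_base, USE.NAMES = FALSE)
}

#' Call SNPs from a marker-gene alignment
#'
#' Reports one record per alignment column carrying at least two distinct
#' non-gap, non-N bases. Polarity is set by an explicit reference taxon:
#' for a biallelic column the derived base is the single alternate, typed
#' by [classify_substitution()] and labelled by [ta_effect()]; columns
#' with three or more bases, or where the reference itself is gapped, are
#' retained as `multiallelic` (the latter with `ref_gap = TRUE` and a
#' warning) and excluded from Ts/Tv and A/T-effect summaries.
#'
#' @param alignment a tibble with `taxon` and `sequence` columns.
#' @param reference reference taxon label; defaults to the first row.
#' @return a tibble with one row per variable column: `position`,
#'   `change_type`, `change` (e.g. `"A>G"`), `reference_base`,
#'   `derived_base`, `ta_effect`, `ref_gap`, then one allele column per
#'   taxon.
#' @export
call_snps <- function(alignment, reference = NULL) {
  m <- alignment_matrix(alignment)
  if (nrow(m) < 2L) abort("SNP calling needs at least 2 sequences.")
  reference <- reference %||% rownames(m)[1]
  if (!reference %in% rownames(m)) {
    abort(paste0("Reference taxon '", reference, "' not in the alignment."))
  }
  is_base <- m %in% c("A", "C", "G", "T")
  dim(is_base) <- dim(m)
  variable <- which(vapply(seq_len(ncol(m)), function(j) {
    length(unique(m[is_base[, j], j])) >= 2L
  }, logical(1)))
  if (length(variable) == 0L) {
    out <- tibble(position = integer(), change_type = character(),
                  change = character(), reference_base = character(),
                  derived_base = character(), ta_effect = character(),
                  ref_gap = logical())
    for (tx in rownames(m)) out[[tx]] <- character()
    return(out)
  }
  ref_row <- match(reference, rownames(m))
  recs <- map(variable, function(j) {
    bases <- unique(m[is_base[, j], j])
    ref_base <- m[ref_row, j]
    ref_ok <- ref_base %in% c("A", "C", "G", "T")
    if (!ref_ok) {
      type <- "multiallelic"; derived <- NA_character_; eff <- NA_character_
    } else if (length(bases) == 2L) {
      derived <- setdiff(bases, ref_base)
      type <- classify_substitution(ref_base, derived)
      eff <- ta_effect(ref_base, derived)
    } else {
      type <- "multiallelic"; derived <- NA_character_; eff <- NA_character_
    }
    c(list(position = j, change_type = type,
           change = if (is.na(derived)) NA_character_ else
             paste0(ref_base, ">", derived),
           reference_base = if (ref_ok) ref_base else NA_character_,
           derived_base = derived, ta_effect = eff, ref_gap = !ref_ok),
      as.list(setNames(m[, j], rownames(m))))
  })
  if (any(map_lgl(recs, "ref_gap"))) {
    warn("Reference taxon is gapped at one or more variable sites; those sites are reported as multiallelic.")
  }
  mutate(bind_rows(lapply(recs, as_tibble)),
         position = as.integer(.data$position))
}

#' Pairwise sequence identity of two aligned rows
#'
#' Identity over the columns where neither row has a gap or `N`:
#' `matches / compared * 100`, half-up rounded at 2 decimals.
#'
#' @param row_i,row_j equal-length aligned sequence strings.
#' @return a one-row tibble: `percent`, `compared_length`.
#' @examples
#' a <- strrep("A", 423)
#' b <- paste0(strrep("A", 422), "G")
#' pairwise_identity(a, b)  # 99.76 over 423 columns
#' @export
pairwise_identity <- function(row_i, row_j) {
  stopifnot(is.character(row_i), is.character(row_j),
            length(row_i) == 1L, length(row_j) == 1L)
  if (nchar(row_i) != nchar(row_j)) abort("Rows differ in length.")
  ci <- strsplit(row_i, "", fixed = TRUE)[[1]]
  cj <- strsplit(row_j, "", fixed = TRUE)[[1]]
  ok <- ci %in% c("A", "C", "G", "T") & cj %in% c("A", "C", "G", "T")
  if (!any(ok)) abort("No comparable (gap-free) columns.")
  tibble(percent = round_half_up(100 * sum(ci[ok] == cj[ok]) / sum(ok), 2),
         compared_length = sum(ok))
}

#' All-pairs identity matrix of an alignment
#'
#' @param alignment a tibble with `taxon` and `sequence` columns.
#' @return an object of class `identity_matrix`: a list with `percent`
#'   (symmetric matrix, diagonal 100.00) and `compared_length`.
#'   [generics::tidy()] gives the pairs as a tibble.
#' @export
identity_matrix <- function(alignment) {
  n <- nrow(alignment)
  taxa <- alignment$taxon
  pct <- matrix(100, n, n, dimnames = list(taxa, taxa))
  len <- matrix(NA_integer_, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n)) {
    ci <- strsplit(alignment$sequence[i], "", fixed = TRUE)[[1]]
    oki <- ci %in% c("A", "C", "G", "T")
    len[i, i] <- sum(oki)
    for (j in seq_len(i - 1L)) {
      p <- pairwise_identity(alignment$sequence[i], alignment$sequence[j])
      pct[i, j] <- pct[j, i] <- p$percent
      len[i, j] <- len[j, i] <- p$compared_length
    }
  }
  structure(list(percent = pct, compared_length = len),
            class = "identity_matrix")
}

#' @export
print.identity_matrix <- function(x, ...) {
  cat("Pairwise identity (%):\n")
  print(round(x$percent, 2))
  invisible(x)
}

#' Group-diagnostic and private-allele sites
#'
#' A shared diagnostic site is a gap-free column where every member of the
#' group carries one base and every non-member carries a single different
#' base. A private-allele site is a gap-free column where exactly one
#' taxon differs from all the (mutually identical) others.
#'
#' @param alignment a tibble with `taxon` and `sequence` columns.
#' @param group character vector of taxa forming a non-empty proper subset.
#' @return a list: `shared_diagnostic` (integer positions) and
#'   `private_alleles` (tibble `taxon`, `position`).
#' @export
diagnostic_sites <- function(alignment, group) {
  m <- alignment_matrix(alignment)
  taxa <- rownames(m)
  if (length(group) == 0L || !all(group %in% taxa)) {
    abort("`group` must be a non-empty subset of the alignment's taxa.")
  }
  if (setequal(group, taxa)) {
    abort("`group` must be a proper subset of the taxa.")
  }
  in_group <- taxa %in% group
  is_base <- m %in% c("A", "C", "G", "T")
  dim(is_base) <- dim(m)
  gap_free <- colSums(is_base) == nrow(m)
  shared <- integer()
  priv <- list()
  for (j in which(gap_free)) {
    col <- m[, j]
    g <- unique(col[in_group]); ng <- unique(col[!in_group])
    if (length(g) == 1L && length(ng) == 1L && g != ng) {
      shared <- c(shared, j)
    }
    tab <- table(col)
    if (length(tab) == 2L && min(tab) == 1L && nrow(m) > 2L) {
      minority <- names(tab)[which.min(tab)]
      priv[[length(priv) + 1L]] <- tibble(taxon = taxa[col == minority],
                                          position = j)
    }
  }
  list(
    shared_diagnostic = shared,
    private_alleles = if (length(priv)) bind_rows(priv) else
      tibble(taxon = character(), position = integer())
  )
}

#' Find indels in an alignment
#'
#' Maximal runs of contiguous columns sharing an identical gapped taxon
#' set form one indel event; the retained string is read from the ungapped
#' taxa. A column gapped in every taxon indicates a malformed alignment
#' and is an error.
#'
#' @param alignment a tibble with `taxon` and `sequence` columns.
#' @return a tibble: `start`, `end`, `length`, `inserted_or_deleted` (the
#'   retained string), `taxa_with_gap` (comma-joined labels).
#' @export
find_indels <- function(alignment) {
  m <- alignment_matrix(alignment)
  if (nrow(m) < 2L) abort("Indel detection needs at least 2 sequences.")
  gap <- m == "-"
  if (any(colSums(gap) == nrow(m))) {
    abort("Malformed alignment: a column is gapped in every taxon.")
  }
  pattern <- apply(gap, 2L, function(col) {
    paste(rownames(m)[col], collapse = ",")
  })
  has_gap <- colSums(gap) > 0L
  out <- list()
  j <- 1L
  while (j <= ncol(m)) {
    if (has_gap[j]) {
      k <- j
      while (k < ncol(m) && has_gap[k + 1L] &&
               pattern[k + 1L] == pattern[j]) {
        k <- k + 1L
      }
      carrier <- which(!gap[, j])[1]
      out[[length(out) + 1L]] <- tibble(
        start = j, end = k, length = k - j + 1L,
        inserted_or_deleted = paste(m[carrier, j:k], collapse = ""),
        taxa_with_gap = pattern[j]
      )
      j <- k + 1L
    } else {
      j <- j + 1L
    }
  }
  if (length(out) == 0L) {
    return(tibble(start = integer(), end = integer(), length = integer(),
                  inserted_or_deleted = character(),
                  taxa_with_gap = character()))
  }
  mutate(bind_rows(out), start = as.integer(.data$start),
         end = as.integer(.data$end), length = as.integer(.data$length))
}
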
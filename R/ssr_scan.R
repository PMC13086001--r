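#' MISA-style SSR detection thresholds
#'
#' Minimum repeat counts per motif unit size (1-6). The defaults are the
#' standard MISA settings for plastomes: 10 repeats for mononucleotides, 6
#' for dinucleotides, 4 for tri- and tetranucleotides, 3 for penta- and
#' hexanucleotides.
#'
#' @param mono,di,tri,tetra,penta,hexa minimum repeat counts, all >= 2.
#' @return a named integer vector of length 6.
#' @export
ssr_thresholds <- function(mono = 10, di = 6, tri = 4, tetra = 4,
                           penta = 3, hexa = 3) {
  thr <- c(mono, di, tri, tetra, penta, hexa)
  if (any(!is.finite(thr)) || any(thr < 2) || any(thr != round(thr))) {
    abort("All SSR thresholds must be integers >= 2.")
  }
  setNames(as.integer(thr), as.character(1:6))
}

# TRUE if the motif is not a repetition of a shorter unit.
is_primitive_motif <- function(motif) {
  k <- nchar(motif)
  if (k == 1L) return(TRUE)
  for (d in seq_len(k - 1L)) {
    if (k %% d == 0L &&
        motif == strrep(substr(motif, 1L, d), k / d)) {
      return(FALSE)
    }
  }
  TRUE
}

#' Detect perfect simple sequence repeats
#'
#' Finds every maximal perfect tandem repeat whose primitive unit is 1-6 bp
#' long and whose whole-unit repeat count meets the threshold for that unit
#' size. Motifs are reported as observed on the given strand, with no
#' reverse-complement or cyclic-rotation canonicalisation, so A- and
#' T-homopolymers (and e.g. TAA/ATA/AAT) are counted separately. A run
#' qualifies only at its smallest period, which keeps the unit-size classes
#' disjoint. `N` breaks runs and runs never wrap the origin.
#'
#' A locus spans exactly `unit_size * repeats` bp: trailing partial units
#' are not included in the reported interval.
#'
#' @param sequence genome string over `{A,C,G,T,N}`.
#' @param thresholds see [ssr_thresholds()].
#' @return a tibble sorted by `start`: `motif`, `unit_size`, `repeats`,
#'   `start`, `end`, `length`, `region` (initially `"unassigned"`; see
#'   [assign_ssr_regions()]). Empty sequence gives an empty tibble.
#' @examples
#' detect_ssrs(paste0("G", strrep("A", 10), "CCTGTT"))
#' @export
detect_ssrs <- function(sequence, thresholds = ssr_thresholds()) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  stopifnot(length(thresholds) == 6L)
  empty <- tibble(motif = character(), unit_size = integer(),
                  repeats = integer(), start = integer(), end = integer(),
                  length = integer(), region = character())
  L <- nchar(sequence)
  if (L == 0L) return(empty)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (any(!chars %in% c("A", "C", "G", "T", "N"))) {
    abort("Sequence contains characters outside {A,C,G,T,N}.")
  }
  valid <- chars != "N"
  out <- list()
  for (k in 1:6) {
    thr <- thresholds[[k]]
    if (L < k * thr) next
    i1 <- seq_len(L - k)
    m <- chars[i1] == chars[i1 + k] & valid[i1] & valid[i1 + k]
    r <- rle(m)
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    hit <- which(r$values & r$lengths + k >= k * thr)
    for (h in hit) {
      i <- run_start[h]
      total <- r$lengths[h] + k
      count <- total %/% k
      if (count < thr) next
      motif <- substr(sequence, i, i + k - 1L)
      if (!is_primitive_motif(motif)) next
      out[[length(out) + 1L]] <- list(
        motif = motif, unit_size = k, repeats = count,
        start = i, end = i + count * k - 1L
      )
    }
  }
  if (length(out) == 0L) return(empty)
  loci <- bind_rows(lapply(out, as_tibble))
  loci <- mutate(loci,
                 unit_size = as.integer(.data$unit_size),
                 repeats = as.integer(.data$repeats),
                 start = as.integer(.data$start),
                 end = as.integer(.data$end),
                 length = .data$end - .data$start + 1L,
                 region = "unassigned")
  arrange(loci, .data$start, .data$unit_size)
}

#' Assign SSR loci to quadripartite regions
#'
#' A locus belongs to the region containing its start coordinate; a locus
#' straddling a junction is therefore assigned to its region of origin.
#'
#' @param loci a [detect_ssrs()] tibble.
#' @param partition a [build_partition()] result.
#' @return `loci` with the `region` column filled in.
#' @export
assign_ssr_regions <- function(loci, partition) {
  validate_partition(partition)
  if (nrow(loci) == 0L) return(loci)
  total <- partition_total(partition)
  if (any(loci$start < 1 | loci$end > total)) {
    abort(paste0("SSR locus outside [1, ", total, "]."))
  }
  mutate(loci, region = region_of(.data$start, partition))
}

#' Genome-level SSR summary statistics
#'
#' Counts and densities of SSR loci by unit size and by region, overall
#' density per kb, mononucleotide base composition and the mononucleotide
#' length distribution.
#'
#' Densities are `count / region_length` scaled to 100 kb per region (per
#' kb genome-wide), half-up rounded at 2 decimals; full-precision values
#' are kept alongside.
#'
#' @param loci region-assigned loci (see [assign_ssr_regions()]).
#' @param partition a [build_partition()] result.
#' @param genome_length defaults to `partition_total(partition)`.
#' @return an object of class `ssr_summary`: a list with `total`,
#'   `by_unit_size`, `by_region`, `density_per_kb` (a [report_value()]),
#'   `mono_composition`, `mono_length_histogram`, `genome_length`.
#' @export
ssr_summary <- function(loci, partition, genome_length = NULL) {
  validate_partition(partition)
  genome_length <- genome_length %||% partition_total(partition)
  if (any(partition$length == 0L)) abort("Zero-length region in partition.")
  if (nrow(loci) > 0L && any(loci$region == "unassigned")) {
    loci <- assign_ssr_regions(loci, partition)
  }
  total <- nrow(loci)
  by_unit <- left_join(tibble(unit_size = 1:6),
                       count(loci, .data$unit_size),
                       by = "unit_size")
  by_unit$n[is.na(by_unit$n)] <- 0L
  regions <- as.character(partition$region)
  per_region <- map(1:6, function(k) {
    cnt <- table(factor(loci$region[loci$unit_size == k], levels = regions))
    as.integer(cnt)
  })
  n_region <- as.integer(table(factor(loci$region, levels = regions)))
  by_region <- tibble(
    region = regions,
    size_bp = partition$length,
    n_ssrs = n_region,
    pct = if (total > 0) round_half_up(100 * n_region / total, 2) else 0
  )
  for (k in 1:6) by_region[[paste0("p", k)]] <- per_region[[k]]
  by_region$density_per_100kb_raw <- by_region$n_ssrs / by_region$size_bp * 1e5
  by_region$density_per_100kb <- round_half_up(by_region$density_per_100kb_raw, 2)
  mono <- loci[loci$unit_size == 1L, , drop = FALSE]
  mono_counts <- table(factor(mono$motif, levels = c("A", "T", "C", "G")))
  hist <- count(mono, length = .data$length)
  if (nrow(hist) > 0L) {
    hist$pct <- round_half_up(100 * hist$n / nrow(mono), 1)
  } else {
    hist$pct <- numeric()
  }
  structure(
    list(
      total = total,
      by_unit_size = by_unit,
      by_region = by_region,
      density_per_kb = report_value(total / genome_length * 1000, 2,
                                    units = "SSRs/kb"),
      # unlike mono_composition(), the summary tolerates degenerate
      # compositions (no mono loci, or no A-homopolymer): ratio/shares NA
      mono_composition = if (nrow(mono) > 0L) {
        tibble(n_mono = nrow(mono),
               A = as.integer(mono_counts[["A"]]),
               T = as.integer(mono_counts[["T"]]),
               C = as.integer(mono_counts[["C"]]),
               G = as.integer(mono_counts[["G"]]),
               pct_A = round_half_up(100 * mono_counts[["A"]] / nrow(mono), 0),
               pct_T = round_half_up(100 * mono_counts[["T"]] / nrow(mono), 0),
               ta_ratio = if (mono_counts[["A"]] > 0) {
                 round_half_up(mono_counts[["T"]] / mono_counts[["A"]], 2)
               } else {
                 NA_real_
               })
      } else {
        tibble(n_mono = 0L, A = 0L, T = 0L, C = 0L, G = 0L,
               pct_A = NA_real_, pct_T = NA_real_, ta_ratio = NA_real_)
      },
      mono_length_histogram = hist,
      genome_length = genome_length
    ),
    class = "ssr_summary"
  )
}

#' @export
print.ssr_summary <- function(x, ...) {
  cat("SSR summary:", x$total, "loci over", x$genome_length, "bp (",
      format(x$density_per_kb), ")\n", sep = " ")
  cat("\nBy region:\n")
  print(as.data.frame(x$by_region[, c("region", "size_bp", "n_ssrs", "pct",
                                      paste0("p", 1:4),
                                      "density_per_100kb")]),
        row.names = FALSE)
  cat("\nMononucleotide composition:\n")
  print(as.data.frame(x$mono_composition), row.names = FALSE)
  invisible(x)
}

#' Mononucleotide SSR base composition
#'
#' Counts of A/T/C/G homopolymer loci, the A and T percentages over all
#' mononucleotide loci (integer precision), and the T/A ratio (2 decimals)
#' — the compositional gradient statistic used to compare species.
#'
#' @param loci an SSR locus tibble (only `unit_size == 1` rows are used).
#' @return one-row tibble: `n_mono`, `A`, `T`, `C`, `G`, `pct_A`, `pct_T`,
#'   `ta_ratio`.
#' @examples
#' loci <- tibble::tibble(motif = c(rep("A", 39), rep("T", 44)),
#'                        unit_size = 1L)
#' mono_composition(loci)  # 47% A, 53% T, T/A = 1.13
#' @export
mono_composition <- function(loci) {
  mono <- loci[loci$unit_size == 1L, , drop = FALSE]
  if (nrow(mono) == 0L) abort("No mononucleotide loci.")
  cnt <- table(factor(mono$motif, levels = c("A", "T", "C", "G")))
  a <- as.integer(cnt[["A"]]); t <- as.integer(cnt[["T"]])
  if (a == 0L) abort("T/A ratio undefined: no A-homopolymer loci.")
  tibble(
    n_mono = nrow(mono),
    A = a, T = t, C = as.integer(cnt[["C"]]), G = as.integer(cnt[["G"]]),
    pct_A = round_half_up(100 * a / nrow(mono), 0),
    pct_T = round_half_up(100 * t / nrow(mono), 0),
    ta_ratio = round_half_up(t / a, 2)
  )
}
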
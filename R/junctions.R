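#' Detect the inverted-repeat structure of a plastome
#'
#' Locates the longest pair of disjoint, exact reverse-complement
#' substrings of at least `min_ir_length` bp and returns the quadripartite
#' partition, labelling the longer single-copy stretch LSC. Detection is
#' exact-match: a near-identical IR pair containing internal mismatches is
#' reported as its longest exact core.
#'
#' The search seeds k-mers (`k = min(32, min_ir_length)`) at a stride that
#' guarantees a seed inside any qualifying repeat, matches them against the
#' reverse complement, and extends each match along its antidiagonal to the
#' maximal exact reverse-complement pairing.
#'
#' The input must be linearised at the LSC start (the conventional origin,
#' the frame in which all coordinates are reported); a genome whose
#' detected structure cannot be expressed as LSC->IRb->SSC->IRa from
#' position 1 is an error, as is a sequence without a qualifying repeat
#' pair. If the two single-copy stretches tie in length, the one containing
#' position 1 is labelled LSC, with a warning.
#'
#' @param sequence genome string over `{A,C,G,T,N}`; length must exceed
#'   `2 * min_ir_length`.
#' @param min_ir_length minimum IR length in bp (default 1000).
#' @return a `region_partition` (see [build_partition()]).
#' @seealso [find_longest_inverted_repeat()] for the raw repeat pair
#'   without the quadripartite frame.
#' @export
detect_inverted_repeats <- function(sequence, min_ir_length = 1000) {
  best <- find_longest_inverted_repeat(sequence, min_ir_length)
  L <- nchar(sequence)
  b1 <- best$irb_start; b2 <- best$irb_end
  a1 <- best$ira_start; a2 <- best$ira_end
  inner <- a1 - b2 - 1L
  outer <- (b1 - 1L) + (L - a2)
  if (inner <= 0L || outer <= 0L) {
    abort("No quadripartite structure: a single-copy stretch is empty.")
  }
  if (inner == outer) {
    warn("Single-copy stretches tie in length; labelling the stretch containing position 1 as LSC.")
  }
  if (inner > outer) {
    abort(paste0("The longer single-copy stretch lies between the repeats; ",
                 "the genome is not linearised at the LSC start ",
                 "(circular rotation search is not supported)."))
  }
  if (a2 != L || b1 == 1L) {
    abort(paste0("Detected repeats at [", b1, ",", b2, "] and [", a1, ",",
                 a2, "] do not fit the LSC->IRb->SSC->IRa frame from ",
                 "position 1; linearise the genome at the LSC start."))
  }
  build_partition(lsc_len = b1 - 1L, irb_len = b2 - b1 + 1L,
                  ssc_len = inner, ira_len = a2 - a1 + 1L)
}

#' Locate the longest exact inverted-repeat pair
#'
#' The longest pair of disjoint, exact reverse-complement substrings of at
#' least `min_ir_length` bp, regardless of whether the implied
#' quadripartite frame is expressible from position 1 — e.g. for a
#' near-identical IR pair whose internal mismatch splits the exact match,
#' this reports the longest exact flank pair.
#'
#' @inheritParams detect_inverted_repeats
#' @return a one-row tibble: `irb_start`, `irb_end`, `ira_start`,
#'   `ira_end`, `length`.
#' @export
find_longest_inverted_repeat <- function(sequence, min_ir_length = 1000) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  L <- nchar(sequence)
  if (L <= 2 * min_ir_length) {
    abort("Sequence shorter than twice `min_ir_length`.")
  }
  k <- min(32L, as.integer(min_ir_length))
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  comp <- chartr("ACGTN", "TGCAN", chars)
  rc <- paste(rev(comp), collapse = "")
  pos <- seq_len(L - k + 1L)
  rkms <- substring(rc, pos, pos + k - 1L)
  stride <- max(1L, (as.integer(min_ir_length) - k) %/% 2L)
  seeds <- seq(1L, L - k + 1L, by = stride)
  seed_kms <- substring(sequence, seeds, seeds + k - 1L)
  # collect candidate antidiagonals D = a + b over pairing (a, b)
  diag_seed <- integer()
  for (s in seq_along(seeds)) {
    if (grepl("N", seed_kms[s], fixed = TRUE)) next
    ps <- which(rkms == seed_kms[s])
    if (length(ps) > 50L) ps <- ps[seq_len(50L)]
    for (p in ps) {
      D <- seeds[s] + L - p + 1L
      if (is.na(diag_seed[as.character(D)] %||% NA)) {
        diag_seed[as.character(D)] <- seeds[s]
      }
    }
  }
  best <- NULL
  for (Dc in names(diag_seed)) {
    D <- as.integer(Dc)
    lo <- max(1L, D - L)
    hi <- min(L, D - 1L)
    a_idx <- lo:hi
    ok <- chars[a_idx] == comp[D - a_idx] & chars[a_idx] != "N"
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    # a mismatch inside a near-identical pair splits the antidiagonal
    # into several exact runs; every run is a candidate flank pair
    for (h in which(r$values)) {
      u <- a_idx[starts[h]]
      v <- a_idx[ends[h]]
      amax <- min(v, (D - 1L) %/% 2L)
      if (amax < u) next
      len <- amax - u + 1L
      if (is.null(best) || len > best$len ||
          (len == best$len && u < best$u)) {
        best <- list(u = u, amax = amax, D = D, len = len)
      }
    }
  }
  if (is.null(best) || best$len < min_ir_length) {
    abort(paste0("No quadripartite structure: no disjoint exact ",
                 "reverse-complement pair of length >= ", min_ir_length,
                 " bp found."))
  }
  tibble(irb_start = best$u, irb_end = best$amax,
         ira_start = best$D - best$amax, ira_end = best$D - best$u,
         length = best$len)
}

#' Gene spans across IR/SC junctions
#'
#' For each gene that crosses one of the four region boundaries (LSC/IRb,
#' IRb/SSC, SSC/IRa, IRa/LSC is absent in the linearised frame), reports
#' how many bp lie in the region before and after the junction. Genes
#' wholly inside one region contribute no rows; a gene crossing two or more
#' junctions signals a malformed annotation and is an error.
#'
#' @param genes a tibble with `gene_id`, `start`, `end` (1-based
#'   inclusive), e.g. from [read_gene_gff3()].
#' @param partition a [build_partition()] result.
#' @return a tibble: `gene_id`, `junction` (e.g. `"LSC/IRb"`),
#'   `region_upstream`, `region_downstream`, `span_upstream`,
#'   `span_downstream` (bp; they sum to the gene length).
#' @examples
#' p <- build_partition(91462, 26659, 18285, 26659)
#' g <- tibble::tibble(gene_id = "rpl22", start = 91106, end = 91528)
#' junction_spans(g, p)  # 357 bp in LSC, 66 bp in IRb
#' @export
junction_spans <- function(genes, partition) {
  validate_partition(partition)
  stopifnot(is.data.frame(genes),
            all(c("gene_id", "start", "end") %in% names(genes)))
  total <- partition_total(partition)
  if (nrow(genes) == 0L) {
    return(tibble(gene_id = character(), junction = character(),
                  region_upstream = character(),
                  region_downstream = character(),
                  span_upstream = integer(), span_downstream = integer()))
  }
  if (any(genes$start < 1 | genes$end > total | genes$start > genes$end)) {
    abort(paste0("Gene interval outside [1, ", total, "]."))
  }
  r1 <- findInterval(genes$start, partition$start)
  r2 <- findInterval(genes$end, partition$start)
  if (any(r2 - r1 >= 2L)) {
    bad <- genes$gene_id[r2 - r1 >= 2L][1]
    abort(paste0("Gene '", bad, "' crosses more than one junction; ",
                 "this is not biologically expected and suggests a bad ",
                 "annotation."))
  }
  crossing <- which(r2 == r1 + 1L)
  regions <- as.character(partition$region)
  tibble(
    gene_id = genes$gene_id[crossing],
    junction = paste0(regions[r1[crossing]], "/", regions[r2[crossing]]),
    region_upstream = regions[r1[crossing]],
    region_downstream = regions[r2[crossing]],
    span_upstream = as.integer(partition$end[r1[crossing]] -
                                 genes$start[crossing] + 1L),
    span_downstream = as.integer(genes$end[crossing] -
                                   partition$start[r2[crossing]] + 1L)
  )
}

#' Across-species junction shift table
#'
#' The "shift" of a region class is the range (max - min) of its length
#' across species — one number per region class, with the IR shift
#' computed on the shared IR length.
#'
#' @param partitions a named list of [build_partition()] results (names are
#'   species), or a tibble with columns `species`, `region`, `length`.
#' @return a tibble: `region_class` (`LSC`, `SSC`, `IR`), `min_bp`,
#'   `max_bp`, `shift_bp`.
#' @export
junction_shift_table <- function(partitions) {
  if (is.data.frame(partitions)) {
    long <- partitions
    stopifnot(all(c("species", "region", "length") %in% names(long)))
  } else {
    if (length(partitions) == 0L) abort("No partitions supplied.")
    stopifnot(is.list(partitions), !is.null(names(partitions)))
    long <- bind_rows(lapply(names(partitions), function(sp) {
      p <- partitions[[sp]]
      validate_partition(p)
      tibble(species = sp, region = as.character(p$region),
             length = p$length)
    }))
  }
  if (length(unique(long$species)) < 2L) {
    abort("Junction shifts need at least 2 species.")
  }
  long$region_class <- ifelse(long$region %in% c("IRa", "IRb"), "IR",
                              long$region)
  # the IR shift is computed on the shared IR length (one copy per species)
  long <- distinct(long, .data$species, .data$region_class,
                   .keep_all = TRUE)
  out <- summarise(group_by(long, .data$region_class),
                   min_bp = min(.data$length),
                   max_bp = max(.data$length),
                   shift_bp = max(.data$length) - min(.data$length),
                   .groups = "drop")
  out[match(c("LSC", "SSC", "IR"), out$region_class), ]
}
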
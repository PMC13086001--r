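#' Build a quadripartite region partition
#'
#' Lays out the canonical plastome frame LSC -> IRb -> SSC -> IRa as
#' contiguous 1-based inclusive intervals starting at position 1. The two
#' inverted-repeat copies must be equal in length, and by convention the
#' large single-copy region is the longer of the two single-copy stretches.
#'
#' @param lsc_len,irb_len,ssc_len,ira_len region lengths in bp; all > 0 and
#'   `irb_len == ira_len`.
#' @return a `region_partition`: a tibble with columns `region`
#'   (`LSC`,`IRb`,`SSC`,`IRa`), `start`, `end`, `length`, and attribute
#'   `total`.
#' @examples
#' build_partition(91462, 26659, 18285, 26659)  # a 163,065 bp plastome
#' @export
build_partition <- function(lsc_len, irb_len, ssc_len, ira_len) {
  lens <- c(LSC = lsc_len, IRb = irb_len, SSC = ssc_len, IRa = ira_len)
  if (any(!is.finite(lens)) || any(lens <= 0) || any(lens != round(lens))) {
    abort("All region lengths must be positive integers.")
  }
  if (irb_len != ira_len) {
    abort(paste0("Inverted repeat copies must be equal in length (IRb = ",
                 irb_len, ", IRa = ", ira_len, ")."))
  }
  if (lsc_len < ssc_len) {
    warn("LSC is shorter than SSC; the canonical frame expects LSC to be the longer single-copy region.")
  }
  ends <- cumsum(lens)
  starts <- c(1, head(ends, -1) + 1)
  out <- tibble(
    region = factor(names(lens), levels = names(lens)),
    start = as.integer(starts),
    end = as.integer(ends),
    length = as.integer(lens)
  )
  attr(out, "total") <- as.integer(ends[[4]])
  class(out) <- c("region_partition", class(out))
  out
}

#' Total length of a partition
#' @param partition a [build_partition()] result.
#' @return genome length in bp.
#' @export
partition_total <- function(partition) {
  validate_partition(partition)
  attr(partition, "total")
}

validate_partition <- function(partition) {
  if (!inherits(partition, "region_partition")) {
    abort("Expected a `region_partition` (see build_partition()).")
  }
  stopifnot(nrow(partition) == 4L,
            identical(as.character(partition$region),
                      c("LSC", "IRb", "SSC", "IRa")))
  with(partition, {
    stopifnot(all(start <= end),
              all(start[-1] == end[-4] + 1L),
              start[1] == 1L,
              length[2] == length[4])
  })
  stopifnot(identical(attr(partition, "total"), partition$end[4]))
  invisible(partition)
}

#' Which region contains each position
#'
#' @param position integer vector of 1-based genome positions.
#' @param partition a [build_partition()] result.
#' @return character vector of region labels.
#' @export
region_of <- function(position, partition) {
  validate_partition(partition)
  total <- partition_total(partition)
  if (any(position < 1 | position > total)) {
    abort(paste0("Position outside [1, ", total, "]."))
  }
  idx <- findInterval(position, partition$start)
  as.character(partition$region)[idx]
}

#' Extract the substring of one region
#'
#' @param sequence genome sequence string.
#' @param partition a [build_partition()] result.
#' @param region one of `"LSC"`, `"IRb"`, `"SSC"`, `"IRa"`.
#' @return the region's subsequence.
#' @export
region_sequence <- function(sequence, partition, region) {
  validate_partition(partition)
  region <- match.arg(region, c("LSC", "IRb", "SSC", "IRa"))
  if (nchar(sequence) != partition_total(partition)) {
    abort("Sequence length does not match the partition total.")
  }
  i <- match(region, as.character(partition$region))
  substr(sequence, partition$start[i], partition$end[i])
}

#' Reverse complement of a DNA string
#'
#' `N` and the gap character are preserved.
#'
#' @param sequence DNA string over `{A,C,G,T,N,-}`.
#' @return the reverse complement string.
#' @export
reverse_complement <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  chartr("ACGTN-", "TGCAN-",
         paste(rev(strsplit(sequence, "", fixed = TRUE)[[1]]), collapse = ""))
}

#' GC content of a sequence or interval
#'
#' `(G + C) / (A + C + G + T)`; `N` is excluded from the denominator.
#'
#' @param sequence DNA string.
#' @param start,end optional 1-based inclusive interval; defaults to the
#'   whole sequence.
#' @return the GC fraction (in `[0, 1]`). Multiply by 100 and wrap with
#'   [report_value()] to print a percentage at 2 decimals.
#' @examples
#' gc_content("GCGC")  # 1
#' gc_content("ATGCNN")  # 0.5
#' @export
gc_content <- function(sequence, start = NULL, end = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            nchar(sequence) > 0L)
  if (!is.null(start) || !is.null(end)) {
    start <- start %||% 1L
    end <- end %||% nchar(sequence)
    if (start < 1 || end > nchar(sequence) || start > end) {
      abort("Interval outside the sequence.")
    }
    sequence <- substr(sequence, start, end)
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  gc <- sum(chars %in% c("G", "C"))
  acgt <- sum(chars %in% c("A", "C", "G", "T"))
  if (acgt == 0L) abort("GC content undefined: no A/C/G/T bases in interval.")
  gc / acgt
}
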
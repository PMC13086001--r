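# Run code with a private, seeded RNG stream, restoring the caller's state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n, gc = 0.35) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

#' Specification for a synthetic quadripartite plastome
#'
#' Describes the study conditions a generated genome must realise: region
#' lengths, background GC, SSRs planted at known offsets, and genes
#' planted across junctions. Defaults give a compact quadripartite frame
#' (LSC 10 kb, IR 3 kb, SSC 2 kb — LSC the longest region, SSC the
#' shortest) at the 35% GC typical of plastomes.
#'
#' Planted SSRs are given per region (`LSC`, `IRb`, `SSC`) with a 1-based
#' `offset` inside the region; an SSR planted in IRb is automatically
#' mirrored in IRa by the reverse-complement identity, and the mirrored
#' locus is part of the truth set. Planting directly in IRa is an error.
#'
#' @param lsc,ir,ssc region lengths in bp.
#' @param gc background GC fraction.
#' @param ssrs a tibble `motif`, `repeats`, `region`, `offset`, or `NULL`.
#' @param genes a tibble `gene_id`, `junction` (`"LSC/IRb"`, `"IRb/SSC"`,
#'   `"SSC/IRa"`), `upstream_bp`, `downstream_bp`, or `NULL`.
#' @param thresholds [ssr_thresholds()] the truth set is defined against.
#' @return a list of class `plastome_spec`.
#' @export
plastome_spec <- function(lsc = 10000, ir = 3000, ssc = 2000, gc = 0.35,
                          ssrs = NULL, genes = NULL,
                          thresholds = ssr_thresholds()) {
  stopifnot(lsc > 0, ir > 0, ssc > 0, gc > 0, gc < 1)
  if (!is.null(ssrs)) {
    stopifnot(all(c("motif", "repeats", "region", "offset") %in% names(ssrs)))
    if (any(!ssrs$region %in% c("LSC", "IRb", "SSC"))) {
      abort("Plant SSRs in LSC, IRb or SSC; the IRa copy is implied by the IR identity.")
    }
  }
  if (!is.null(genes)) {
    stopifnot(all(c("gene_id", "junction", "upstream_bp", "downstream_bp")
                  %in% names(genes)))
    if (any(!genes$junction %in% c("LSC/IRb", "IRb/SSC", "SSC/IRa"))) {
      abort("Gene junctions must be LSC/IRb, IRb/SSC or SSC/IRa.")
    }
  }
  structure(list(lsc = as.integer(lsc), ir = as.integer(ir),
                 ssc = as.integer(ssc), gc = gc, ssrs = ssrs,
                 genes = genes, thresholds = thresholds),
            class = "plastome_spec")
}

#' Generate a synthetic plastome with a machine-readable truth set
#'
#' Builds a quadripartite genome realising a [plastome_spec()]: IRa is the
#' exact reverse complement of IRb, planted SSRs appear at their recorded
#' coordinates, and a rejection loop resamples any background window that
#' would create an unplanned threshold-qualifying SSR, so the returned
#' truth set is exhaustive. Output is a pure function of `(spec, seed)`.
#'
#' @param spec a [plastome_spec()].
#' @param seed integer seed.
#' @param species_id label for the generated genome.
#' @param max_attempts rejection-loop bound (default 1000).
#' @return a list: `species_id`, `sequence`, `partition`, `genes` (tibble
#'   in GFF3-like coordinates), `ssr_truth` (region-assigned loci tibble),
#'   `spec`, `seed`.
#' @export
synth_plastome <- function(spec, seed, species_id = "synthetic",
                           max_attempts = 1000) {
  stopifnot(inherits(spec, "plastome_spec"))
  with_seed(seed, {
    partition <- build_partition(spec$lsc, spec$ir, spec$ssc, spec$ir)
    total <- partition_total(partition)
    chars <- random_dna(total, spec$gc)
    reg <- function(r) partition[match(r, as.character(partition$region)), ]
    irb <- reg("IRb"); ira <- reg("IRa")
    planted <- list()
    if (!is.null(spec$ssrs) && nrow(spec$ssrs) > 0L) {
      for (i in seq_len(nrow(spec$ssrs))) {
        s <- spec$ssrs[i, ]
        k <- nchar(s$motif)
        thr <- spec$thresholds[[k]]
        if (s$repeats < thr) {
          abort(paste0("Planted SSR ", s$motif, "x", s$repeats,
                       " is below the detection threshold (", thr, ")."))
        }
        if (!is_primitive_motif(s$motif)) {
          abort(paste0("Planted motif ", s$motif, " is not primitive."))
        }
        r <- reg(s$region)
        start <- r$start + s$offset - 1L
        end <- start + k * s$repeats - 1L
        if (s$offset < 1L || end > r$end) {
          abort(paste0("Planted SSR ", s$motif, "x", s$repeats,
                       " does not fit inside ", s$region, "."))
        }
        planted[[length(planted) + 1L]] <- tibble(
          motif = s$motif, unit_size = k, repeats = as.integer(s$repeats),
          start = as.integer(start), end = as.integer(end)
        )
        chars[start:end] <- strsplit(strrep(s$motif, s$repeats), "",
                                     fixed = TRUE)[[1]]
      }
    }
    truth <- if (length(planted)) bind_rows(planted) else
      tibble(motif = character(), unit_size = integer(),
             repeats = integer(), start = integer(), end = integer())
    if (nrow(truth) > 1L) {
      o <- order(truth$start)
      if (any(truth$start[o][-1] <= truth$end[o][-nrow(truth)])) {
        abort("Planted SSRs overlap.")
      }
    }
    # mirror IRb-planted loci into IRa (implied by the repeat identity)
    mirror <- filter(truth, .data$start >= irb$start, .data$end <= irb$end)
    if (nrow(mirror) > 0L) {
      truth <- bind_rows(truth, mutate(
        mirror,
        motif = map_chr(.data$motif, reverse_complement),
        start = as.integer(ira$start + (irb$end - .data$end)),
        end = as.integer(ira$start + (irb$end - mirror$start))
      ))
    }
    truth <- mutate(truth, length = .data$end - .data$start + 1L)
    planted_pos <- unlist(map2(truth$start, truth$end, seq))
    mirror_to_irb <- function(p) irb$start + (ira$end - p)
    rebuild <- function(ch) {
      ch[ira$start:ira$end] <- chartr("ACGT", "TGCA",
                                      rev(ch[irb$start:irb$end]))
      ch
    }
    # the planted IR pair must not be chance-extendable into the SSC,
    # or boundary detection would (correctly) report a longer repeat
    ssc_s <- partition$start[3]; ssc_e <- partition$end[3]
    complement1 <- function(x) chartr("ACGT", "TGCA", x)
    fix_ir_edge <- function(ch) {
      while (ch[ssc_s] == complement1(ch[ssc_e])) {
        free <- setdiff(c(ssc_s, ssc_e), planted_pos)
        if (length(free) == 0L) {
          abort("Planted SSRs cover both SSC edges; the IR boundary cannot be pinned.")
        }
        ch[free[1]] <- random_dna(1L, spec$gc)
      }
      ch
    }
    attempt <- 0L
    repeat {
      attempt <- attempt + 1L
      if (attempt > max_attempts) {
        abort("Rejection sampling failed to clear unplanned SSRs.")
      }
      chars <- fix_ir_edge(chars)
      chars <- rebuild(chars)
      genome <- paste(chars, collapse = "")
      det <- detect_ssrs(genome, spec$thresholds)
      key <- function(df) paste(df$motif, df$start, df$end)
      extra <- det[!key(det) %in% key(truth), , drop = FALSE]
      missing <- truth[!key(truth) %in% key(det), , drop = FALSE]
      if (nrow(extra) == 0L && nrow(missing) == 0L) break
      resample <- setdiff(unlist(map2(extra$start, extra$end, seq)),
                          planted_pos)
      if (length(resample) == 0L) {
        # a planted locus got extended by its flank: perturb the flanks
        resample <- setdiff(unique(c(pmax(1L, missing$start - 1L),
                                     pmin(total, missing$end + 1L))),
                            planted_pos)
      }
      in_ira <- resample >= ira$start & resample <= ira$end
      resample <- unique(c(resample[!in_ira],
                           mirror_to_irb(resample[in_ira])))
      chars[resample] <- random_dna(length(resample), spec$gc)
    }
    genes <- NULL
    if (!is.null(spec$genes) && nrow(spec$genes) > 0L) {
      bnd <- setNames(partition$end[1:3],
                      c("LSC/IRb", "IRb/SSC", "SSC/IRa"))
      genes <- tibble(
        gene_id = spec$genes$gene_id,
        start = as.integer(bnd[spec$genes$junction] -
                             spec$genes$upstream_bp + 1L),
        end = as.integer(bnd[spec$genes$junction] +
                           spec$genes$downstream_bp),
        strand = "+",
        feature_class = "protein_coding"
      )
      if (any(genes$start < 1 | genes$end > total)) {
        abort("Planted gene extends outside the genome.")
      }
    }
    list(species_id = species_id,
         sequence = genome,
         partition = partition,
         genes = genes %||% tibble(gene_id = character(), start = integer(),
                                   end = integer(), strand = character(),
                                   feature_class = character()),
         ssr_truth = assign_ssr_regions(arrange(truth, .data$start),
                                        partition),
         spec = spec, seed = seed)
  })
}

#' Write a synthetic plastome bundle to disk
#'
#' Emits the genome FASTA, a GFF3 with the planted gene annotations, and a
#' JSON truth file (partition and SSR truth set).
#'
#' @param plastome a [synth_plastome()] result.
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_synth_bundle <- function(plastome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, paste0(plastome$species_id, ".fasta"))
  write_fasta(setNames(plastome$sequence, plastome$species_id), fasta)
  gff <- file.path(dir, paste0(plastome$species_id, ".gff3"))
  lines <- "##gff-version 3"
  if (nrow(plastome$genes) > 0L) {
    lines <- c(lines, sprintf(
      "%s\tplastomics\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
      plastome$species_id, plastome$genes$start, plastome$genes$end,
      plastome$genes$strand, plastome$genes$gene_id,
      plastome$genes$gene_id))
  }
  writeLines(lines, gff)
  truth <- file.path(dir, paste0(plastome$species_id, ".truth.json"))
  jsonlite::write_json(
    list(partition = as.data.frame(plastome$partition),
         ssr_truth = as.data.frame(plastome$ssr_truth),
         seed = plastome$seed),
    truth, auto_unbox = TRUE, digits = NA)
  invisible(c(fasta = fasta, gff3 = gff, truth = truth))
}

#' Specification for a synthetic multi-taxon alignment
#'
#' Describes planted biallelic SNPs, planted indels and independent
#' background substitution noise at per-site rate `theta`. The default
#' `theta = 0.02` matches typical congeneric plastome divergence.
#'
#' @param n_taxa number of rows (taxa are labelled `t1..tn` unless `taxa`
#'   is given).
#' @param length alignment columns.
#' @param theta per-site, per-taxon background substitution probability in
#'   `[0, 0.5)`; applied outside planted SNP and indel columns.
#' @param snps a tibble `position`, `ref`, `alt`, `carriers`
#'   (comma-joined taxon labels), or `NULL`.
#' @param indels a tibble `position`, `length`, `carriers`, or `NULL`.
#' @param taxa optional taxon labels.
#' @return a list of class `alignment_spec`.
#' @export
alignment_spec <- function(n_taxa, length, theta = 0.02, snps = NULL,
                           indels = NULL, taxa = NULL) {
  stopifnot(n_taxa >= 2, length >= 1, theta >= 0, theta < 0.5)
  taxa <- taxa %||% paste0("t", seq_len(n_taxa))
  stopifnot(length(taxa) == n_taxa, !anyDuplicated(taxa))
  indel_cols <- integer()
  if (!is.null(indels)) {
    stopifnot(all(c("position", "length", "carriers") %in% names(indels)))
    indel_cols <- unlist(map2(indels$position,
                              indels$position + indels$length - 1L, seq))
    stopifnot(!anyDuplicated(indel_cols), all(indel_cols >= 1),
              all(indel_cols <= length))
  }
  if (!is.null(snps)) {
    stopifnot(all(c("position", "ref", "alt", "carriers") %in% names(snps)))
    if (anyDuplicated(snps$position)) abort("Planted SNP positions must be distinct.")
    # keep planted substitutions clear of indel blocks and their edges
    guard <- unique(c(indel_cols, indel_cols - 1L, indel_cols + 1L))
    if (any(snps$position %in% guard)) {
      abort("Planted SNPs must not be adjacent to planted indel blocks.")
    }
    carriers <- strsplit(snps$carriers, ",", fixed = TRUE)
    for (cs in carriers) {
      if (length(cs) == 0L || !all(cs %in% taxa) ||
          length(cs) == n_taxa) {
        abort("Each planted SNP needs a non-empty proper subset of carriers.")
      }
    }
  }
  structure(list(n_taxa = as.integer(n_taxa), length = as.integer(length),
                 theta = theta, snps = snps, indels = indels, taxa = taxa),
            class = "alignment_spec")
}

#' Generate a synthetic alignment with planted variants
#'
#' Realises an [alignment_spec()]: an ancestral sequence is drawn, planted
#' SNP columns get exactly their declared reference/alternate pattern,
#' planted indel carriers get gap blocks, and every other (taxon, site)
#' cell mutates independently to a uniformly chosen different base with
#' probability `theta`. Deterministic under `(spec, seed)`.
#'
#' @param spec an [alignment_spec()].
#' @param seed integer seed.
#' @return a list: `alignment` (tibble `taxon`, `sequence`), `snp_truth`,
#'   `indel_truth`, `spec`, `seed`.
#' @export
synth_alignment <- function(spec, seed) {
  stopifnot(inherits(spec, "alignment_spec"))
  with_seed(seed, {
    anc <- random_dna(spec$length, gc = 0.35)
    m <- matrix(rep(anc, each = spec$n_taxa), nrow = spec$n_taxa)
    rownames(m) <- spec$taxa
    frozen <- integer()
    if (!is.null(spec$snps) && nrow(spec$snps) > 0L) {
      frozen <- c(frozen, spec$snps$position)
    }
    if (!is.null(spec$indels) && nrow(spec$indels) > 0L) {
      frozen <- c(frozen, unlist(map2(
        spec$indels$position,
        spec$indels$position + spec$indels$length - 1L, seq)))
    }
    if (spec$theta > 0) {
      free <- setdiff(seq_len(spec$length), frozen)
      hit <- matrix(runif(spec$n_taxa * length(free)) < spec$theta,
                    nrow = spec$n_taxa)
      for (i in seq_len(spec$n_taxa)) {
        js <- free[hit[i, ]]
        if (length(js)) {
          m[i, js] <- vapply(m[i, js], function(b) {
            sample(setdiff(c("A", "C", "G", "T"), b), 1L)
          }, character(1))
        }
      }
    }
    snp_truth <- NULL
    if (!is.null(spec$snps) && nrow(spec$snps) > 0L) {
      for (i in seq_len(nrow(spec$snps))) {
        s <- spec$snps[i, ]
        cs <- strsplit(s$carriers, ",", fixed = TRUE)[[1]]
        m[, s$position] <- s$ref
        m[cs, s$position] <- s$alt
      }
      snp_truth <- mutate(spec$snps,
                          change_type = classify_substitution(.data$ref,
                                                              .data$alt),
                          ta_effect = ta_effect(.data$ref, .data$alt))
    }
    indel_truth <- NULL
    if (!is.null(spec$indels) && nrow(spec$indels) > 0L) {
      for (i in seq_len(nrow(spec$indels))) {
        d <- spec$indels[i, ]
        cs <- strsplit(d$carriers, ",", fixed = TRUE)[[1]]
        stopifnot(length(cs) >= 1L, length(cs) < spec$n_taxa)
        m[cs, d$position:(d$position + d$length - 1L)] <- "-"
      }
      indel_truth <- mutate(spec$indels,
                            start = .data$position,
                            end = .data$position + .data$length - 1L)
    }
    list(alignment = tibble(taxon = spec$taxa,
                            sequence = unname(apply(m, 1L, paste, collapse = ""))),
         snp_truth = snp_truth %||%
           tibble(position = integer(), ref = character(),
                  alt = character(), carriers = character()),
         indel_truth = indel_truth %||%
           tibble(position = integer(), length = integer(),
                  carriers = character()),
         spec = spec, seed = seed)
  })
}

# Diagnostic alleles of the rpl22 marker for the four section Euphorbia
# species: column -> c(drupifera, resinifera, ampliphylla, royleana).
rpl22_snp_table <- function() {
  tibble(
    position = c(223L, 385L, 390L, 391L, 392L, 394L, 396L, 397L, 405L, 409L),
    E_drupifera  = c("A", "A", "A", "T", "A", "G", "A", "G", "T", "C"),
    E_resinifera = c("G", "G", "G", "C", "T", "T", "T", "A", "T", "A"),
    E_ampliphylla = c("G", "G", "G", "C", "T", "T", "T", "A", "T", "A"),
    E_royleana   = c("G", "G", "G", "C", "T", "T", "T", "A", "G", "A")
  )
}

#' Built-in rpl22 marker alignment for section Euphorbia
#'
#' A fixed 4-taxon, 426-column alignment of the rpl22 ribosomal-protein
#' gene for one pachycaul (*E. drupifera*) and three cactiform
#' (*E. resinifera*, *E. ampliphylla*, *E. royleana*) *Euphorbia* species,
#' reconstructed from the published diagnostic alleles: ten substitution
#' columns (positions 223, 385, 390, 391, 392, 394, 396, 397, 405, 409),
#' nine of them shared by the cactiform trio against *E. drupifera* and
#' one (405) private to the Asian *E. royleana*, plus a 3-bp block
#' (retained string `AGC`) present only in *E. drupifera* and deleted in
#' the cactiform taxa. All other columns are invariant.
#'
#' Published descriptions place the trinucleotide deletion at 395-397 in
#' the ungapped gene frame while also listing substitutions at 396/397 in
#' alignment coordinates; since one alignment cannot host both at the same
#' columns, this fixture keeps the printed substitution columns literal
#' and realises the deletion in a neutral block at columns 150-152.
#'
#' @return a list: `alignment` (tibble `taxon`, `sequence`) and `groups`
#'   (tibble `taxon`, `group` with levels `pachycaul`/`cactiform`).
#' @examples
#' fx <- rpl22_alignment()
#' call_snps(fx$alignment, reference = "E_drupifera")
#' @export
rpl22_alignment <- function() {
  alleles <- rpl22_snp_table()
  taxa <- names(alleles)[-1]
  backbone <- with_seed(426L, random_dna(426L, gc = 0.38))
  m <- matrix(rep(backbone, each = 4L), nrow = 4L,
              dimnames = list(taxa, NULL))
  for (i in seq_len(nrow(alleles))) {
    m[, alleles$position[i]] <- unlist(alleles[i, taxa])
  }
  m["E_drupifera", 150:152] <- c("A", "G", "C")
  m[c("E_resinifera", "E_ampliphylla", "E_royleana"), 150:152] <- "-"
  list(
    alignment = tibble(taxon = taxa,
                       sequence = unname(apply(m, 1L, paste, collapse = ""))),
    groups = tibble(taxon = taxa,
                    group = c("pachycaul", "cactiform", "cactiform",
                              "cactiform"))
  )
}
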
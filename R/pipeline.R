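#' Read a flat key-value run configuration
#'
#' One `key: value` pair per line (DCF format). Values are kept as
#' strings; [run_pipeline()] coerces what it needs.
#'
#' @param path path to the config file.
#' @return a named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("Config file not found: ", path))
  dcf <- read.dcf(path)
  setNames(as.list(as.character(dcf[1, ])), colnames(dcf))
}

write_phylip_dist <- function(d, path) {
  m <- as.matrix(d)
  lines <- c(as.character(nrow(m)),
             vapply(seq_len(nrow(m)), function(i) {
               paste(c(format(rownames(m)[i], width = 10),
                       formatC(m[i, ], format = "f", digits = 6)),
                     collapse = "  ")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

read_square_matrix_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  stats::as.dist(m)
}

pipeline_stage <- function(stage, code) {
  t0 <- Sys.time()
  out <- tryCatch(force(code), error = function(e) {
    abort(paste0("Stage '", stage, "' failed: ", conditionMessage(e)))
  })
  message(sprintf("[%s] done in %.2fs", stage,
                  as.numeric(Sys.time() - t0, units = "secs")))
  out
}

#' Run the plastome analysis pipeline
#'
#' Executes the stages implied by the supplied inputs, in dependency
#' order, and writes TSV/JSON/Newick reports. Stages:
#'
#' * `fasta` (+ optional `gff3`): per-genome IR detection, SSR scan and
#'   summary, junction spans.
#' * `fasta` with >= 2 records: motif matrix, balance indices, Sørensen
#'   distances (PHYLIP), Ward.D2 dendrogram (Newick); with
#'   `mantel_against` (a square distance matrix TSV) a seeded Mantel test.
#' * `alignment` (+ optional `reference`, `group`, `gene_map`): sliding
#'   Pi, SNP/indel/identity tables, diagnostic sites, per-gene diversity.
#'
#' Two runs with an identical config and seed produce byte-identical
#' outputs; any stochastic stage therefore requires `seed` in the config,
#' validated before any computation.
#'
#' @param config a named list, or path to a key-value file
#'   ([read_run_config()]). Recognised keys: `out_dir` (required),
#'   `fasta`, `gff3`, `min_ir`, `thresholds` (comma list of 6),
#'   `alignment`, `reference`, `group` (`label:taxon1,taxon2,...`),
#'   `gene_map`, `window`, `step`, `mantel_against`, `permutations`,
#'   `seed`.
#' @return a tibble of written outputs (`stage`, `path`), invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(is.list(config))
  if (is.null(config$out_dir)) abort("Config must name an `out_dir`.")
  # validate before any computation
  if (!is.null(config$mantel_against) && is.null(config$seed)) {
    abort("Config names `mantel_against` but no `seed`: the Mantel permutation test requires an explicit seed.")
  }
  for (key in c("fasta", "gff3", "alignment", "gene_map", "mantel_against")) {
    if (!is.null(config[[key]]) && !file.exists(config[[key]])) {
      abort(paste0("Input file for `", key, "` not found: ", config[[key]]))
    }
    if (!is.null(config[[key]])) {
      message(sprintf("input %s: %s (md5 %s)", key, config[[key]],
                      unname(tools::md5sum(config[[key]]))))
    }
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  emit <- function(stage, path) {
    out[[length(out) + 1L]] <<- tibble(stage = stage, path = path)
  }
  thresholds <- if (!is.null(config$thresholds)) {
    do.call(ssr_thresholds,
            as.list(as.integer(strsplit(config$thresholds, ",")[[1]])))
  } else {
    ssr_thresholds()
  }
  if (!is.null(config$fasta)) {
    genomes <- pipeline_stage("read", read_plastome_fasta(config$fasta))
    min_ir <- as.integer(config$min_ir %||% 1000L)
    parts <- pipeline_stage("partition", {
      setNames(lapply(genomes$sequence, detect_inverted_repeats,
                      min_ir_length = min_ir), genomes$species)
    })
    ptab <- bind_rows(lapply(names(parts), function(sp) {
      dplyr::bind_cols(tibble(species = sp), as_tibble(parts[[sp]]))
    }))
    p_path <- file.path(config$out_dir, "partitions.tsv")
    write_tsv_report(ptab, p_path); emit("partition", p_path)
    loci <- pipeline_stage("ssr_scan", bind_rows(lapply(
      seq_len(nrow(genomes)), function(i) {
        l <- detect_ssrs(genomes$sequence[i], thresholds)
        l <- assign_ssr_regions(l, parts[[genomes$species[i]]])
        dplyr::bind_cols(tibble(species = genomes$species[i]), l)
      })))
    l_path <- file.path(config$out_dir, "ssr_loci.tsv")
    write_tsv_report(loci, l_path); emit("ssr_scan", l_path)
    summaries <- lapply(genomes$species, function(sp) {
      s <- ssr_summary(loci[loci$species == sp, -1],
                       parts[[sp]])
      list(total = s$total,
           density_per_kb = s$density_per_kb$rounded,
           by_region = as.data.frame(s$by_region),
           mono_composition = as.data.frame(s$mono_composition))
    })
    s_path <- file.path(config$out_dir, "ssr_summary.json")
    jsonlite::write_json(setNames(summaries, genomes$species), s_path,
                         auto_unbox = TRUE, digits = NA)
    emit("ssr_summary", s_path)
    if (!is.null(config$gff3)) {
      spans <- pipeline_stage("junctions", bind_rows(lapply(
        genomes$species, function(sp) {
          genes <- read_gene_gff3(config$gff3, seq_id = sp)
          if (nrow(genes) == 0L) return(NULL)
          dplyr::bind_cols(tibble(species = sp),
                           junction_spans(genes, parts[[sp]]))
        })))
      j_path <- file.path(config$out_dir, "junction_spans.tsv")
      write_tsv_report(spans, j_path); emit("junctions", j_path)
      if (length(parts) >= 2L) {
        sh_path <- file.path(config$out_dir, "junction_shifts.tsv")
        write_tsv_report(junction_shift_table(parts), sh_path)
        emit("junctions", sh_path)
      }
    }
    if (nrow(genomes) >= 2L) {
      pipeline_stage("ssr_compare", {
        mm <- build_motif_matrix(loci)
        b_path <- file.path(config$out_dir, "balance_index.tsv")
        write_tsv_report(balance_index(mm), b_path)
        emit("ssr_compare", b_path)
        d <- sorensen_dissimilarity(mm)
        d_path <- file.path(config$out_dir, "sorensen.phylip")
        write_phylip_dist(d, d_path); emit("ssr_compare", d_path)
        n_path <- file.path(config$out_dir, "ward_dendrogram.nwk")
        write_newick(ward_cluster(d), n_path); emit("ssr_compare", n_path)
        if (!is.null(config$mantel_against)) {
          d2 <- read_square_matrix_tsv(config$mantel_against)
          mt <- mantel_test(d, d2,
                            n_permutations =
                              as.integer(config$permutations %||% 999L),
                            seed = as.integer(config$seed))
          m_path <- file.path(config$out_dir, "mantel.json")
          jsonlite::write_json(
            list(r_observed = mt$r_observed, p_value = mt$p_value,
                 n_permutations = mt$n_permutations, seed = mt$seed),
            m_path, auto_unbox = TRUE, digits = NA)
          emit("ssr_compare", m_path)
        }
      })
    }
  }
  if (!is.null(config$alignment)) {
    aln <- pipeline_stage("read_alignment",
                          read_alignment_fasta(config$alignment))
    L <- nchar(aln$sequence[1])
    window <- as.integer(config$window %||% 600L)
    step <- as.integer(config$step %||% 200L)
    if (L >= window) {
      w_path <- file.path(config$out_dir, "pi_windows.tsv")
      write_tsv_report(pipeline_stage("diversity",
                                      sliding_pi(aln, window, step)),
                       w_path)
      emit("diversity", w_path)
    }
    if (!is.null(config$gene_map)) {
      gmap <- readr::read_tsv(config$gene_map, show_col_types = FALSE)
      gd <- pipeline_stage("gene_diversity", gene_diversity(aln, gmap))
      g_path <- file.path(config$out_dir, "gene_diversity.tsv")
      write_tsv_report(gd, g_path); emit("diversity", g_path)
      rv <- regional_variability_summary(gd)
      r_path <- file.path(config$out_dir, "regional_variability.json")
      jsonlite::write_json(list(counts = as.data.frame(rv$counts),
                                variable_share =
                                  as.data.frame(rv$variable_share)),
                           r_path, auto_unbox = TRUE, digits = NA)
      emit("diversity", r_path)
    }
    pipeline_stage("snps", {
      snps <- call_snps(aln, reference = config$reference)
      s_path <- file.path(config$out_dir, "snps.tsv")
      write_tsv_report(snps, s_path); emit("snps", s_path)
      i_path <- file.path(config$out_dir, "indels.tsv")
      write_tsv_report(find_indels(aln), i_path); emit("snps", i_path)
      im <- identity_matrix(aln)
      id_path <- file.path(config$out_dir, "identity.tsv")
      write_tsv_report(dplyr::bind_cols(tibble(taxon = rownames(im$percent)),
                                        as_tibble(im$percent)),
                       id_path)
      emit("snps", id_path)
      if (!is.null(config$group)) {
        parts2 <- strsplit(config$group, ":", fixed = TRUE)[[1]]
        members <- strsplit(parts2[2], ",", fixed = TRUE)[[1]]
        ds <- diagnostic_sites(aln, members)
        dsj <- file.path(config$out_dir, "diagnostic_sites.json")
        jsonlite::write_json(
          list(group = parts2[1],
               shared_diagnostic = ds$shared_diagnostic,
               private_alleles = as.data.frame(ds$private_alleles)),
          dsj, auto_unbox = TRUE, digits = NA)
        emit("snps", dsj)
      }
    })
  }
  invisible(bind_rows(out))
}
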
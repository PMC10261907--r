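#' Pipeline run configuration
#'
#' Defaults reproduce the method's stated settings: 10-base split anchors,
#' 98% identity, 10-base clip limit, 1.2-bit entropy, 25-base long double
#' anchor support, k = 10 microhomologies, kNN k = 50.
#'
#' @param fusions Path to the candidate fusion list (one `geneA::geneB` or
#'   `geneA--geneB` per line).
#' @param fasta,gtf Reference genome FASTA and gene-structure GTF.
#' @param sam Read alignments to the fusion contigs (SAM or BAM).
#' @param out_dir Optional output directory for the report TSV / summary
#'   JSON.
#' @param total_fragments Optional FFPM denominator override; by default the
#'   distinct read names in the SAM (mapped or not) are counted.
#' @param thresholds A [qc_thresholds()] list.
#' @param max_intron Intron shrinking threshold for contig construction.
#' @param microhomology_k Microhomology k-mer length.
#' @param consensus_set Accepted splice dinucleotide pairs.
#' @param ldas_min_anchor,ldas_aggregate LDAS filter settings.
#' @param max_partners Promiscuity cap.
#' @param paralogs Optional paralog pair TSV path.
#' @param cosmic Optional character vector (or file path) of known-fusion
#'   names used for report tagging.
#' @param model Optional `ClusterModel` for category prediction.
#' @param em_use_raw Use raw split+compatible-spanning counts instead of the
#'   EM estimate for FFPM.
#' @param seed Integer seed (recorded; the core pipeline is deterministic).
#' @return List of class `run_config`.
#' @export
run_config <- function(fusions, fasta, gtf, sam, out_dir = NULL,
                       total_fragments = NULL,
                       thresholds = qc_thresholds(), max_intron = 1000L,
                       microhomology_k = 10L, consensus_set = "GTAG",
                       ldas_min_anchor = 25L, ldas_aggregate = FALSE,
                       max_partners = 10L, paralogs = NULL, cosmic = NULL,
                       model = NULL, em_use_raw = FALSE, seed = 1L) {
  structure(as.list(environment()), class = "run_config")
}

parse_fusion_list <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  parts <- lapply(seq_along(lines), function(i) {
    ln <- lines[i]
    sp <- if (grepl("::", ln, fixed = TRUE)) {
      strsplit(ln, "::", fixed = TRUE)[[1]]
    } else if (grepl("--", ln, fixed = TRUE)) {
      strsplit(ln, "--", fixed = TRUE)[[1]]
    } else {
      stop("cannot parse fusion line ", i, ": '", ln,
           "' (expected geneA::geneB or geneA--geneB)")
    }
    if (length(sp) != 2 || !all(nzchar(sp))) {
      stop("cannot parse fusion line ", i, ": '", ln, "'")
    }
    sp
  })
  data.frame(gene_a = vapply(parts, `[`, character(1), 1),
             gene_b = vapply(parts, `[`, character(1), 2),
             stringsAsFactors = FALSE)
}

#' Run the supervised fusion evidence pipeline
#'
#' Orchestrates contig construction, fragment classification, EM
#' quantification, breakpoint feature computation, filtering and (when a
#' model is supplied) category prediction for every candidate fusion, and
#' writes a per-variant report plus a machine-readable summary.
#'
#' @param cfg A [run_config()].
#' @return List with `report` (per-variant data.frame; see package vignette
#'   for the column contract), `filtered` (variants failing filters, with
#'   rules), `summary` (per-fusion status: `validated`,
#'   `filtered:<rules>`, `no_evidence` or `unresolvable`), `total_fragments`
#'   and, when `cfg$out_dir` is set, the output paths.
#' @export
run_inspect <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  set.seed(cfg$seed)
  cand <- parse_fusion_list(cfg$fusions)
  genome <- read_genome(cfg$fasta)
  alr <- read_alignments(cfg$sam)
  total_fragments <- if (!is.null(cfg$total_fragments)) cfg$total_fragments else
    alr$n_fragments
  message("fuseval: ", nrow(cand), " candidate fusions; ",
          total_fragments, " total fragments (",
          if (is.null(cfg$total_fragments)) "counted from SAM" else "configured",
          "); thresholds: anchor>=", cfg$thresholds$min_anchor,
          " identity>=", cfg$thresholds$min_identity,
          " clip<=", cfg$thresholds$max_end_clip,
          " entropy>=", cfg$thresholds$min_entropy,
          " LDAS>=", cfg$ldas_min_anchor,
          " k=", cfg$microhomology_k, " max_partners=", cfg$max_partners)

  status <- setNames(rep("no_evidence", nrow(cand)),
                     paste0(cand$gene_a, "::", cand$gene_b))
  rows <- list()
  for (i in seq_len(nrow(cand))) {
    ga <- cand$gene_a[i]; gb <- cand$gene_b[i]
    fusion_name <- paste0(ga, "::", gb)
    res <- tryCatch({
      models <- load_gene_models(cfg$gtf, gene_ids = unique(c(ga, gb)))
      contig <- build_fusion_contig(models[[ga]], models[[gb]], genome,
                                    max_intron = cfg$max_intron)
      aln <- alr$alignments[alr$alignments$contig == contig$name, , drop = FALSE]
      frags <- classify_alignments(aln, contig, cfg$thresholds)
      bps <- collect_breakpoints(frags, aln, contig)
      if (length(bps) == 0) {
        list(rows = NULL)
      } else {
        ab <- em_assign(bps)
        mh <- find_microhomologies(contig, k = cfg$microhomology_k)
        splits_by_bp <- lapply(bps, function(bp) {
          Filter(function(e) e$class == "SPLIT" &&
                   e$fragment_id %in% bp$split_read_ids, frags)
        })
        vrows <- lapply(seq_along(bps), function(j) {
          bp <- bps[[j]]
          agree <- reference_agreement(bp, contig, cfg$consensus_set)
          est <- if (cfg$em_use_raw) {
            length(bp$split_read_ids) + length(bp$spanning_compatible_ids)
          } else ab$est_total_fragments[j]
          dec <- combine_decisions(
            min_evidence_filter(bp, agree$consensus),
            ldas_filter(bp, splits_by_bp[[j]],
                        min_anchor = cfg$ldas_min_anchor,
                        aggregate = cfg$ldas_aggregate))
          gleft <- map_contig_to_genome(contig$maps[[ga]], bp$left_break)
          gright <- map_contig_to_genome(contig$maps[[gb]], bp$right_break)
          data.frame(
            fusion = fusion_name, contig = contig$name,
            gene_a = ga, gene_b = gb,
            left_break = bp$left_break, right_break = bp$right_break,
            left_chrom = models[[ga]]$chrom, left_genome = gleft + 1L,
            left_strand = models[[ga]]$strand,
            right_chrom = models[[gb]]$chrom, right_genome = gright + 1L,
            right_strand = models[[gb]]$strand,
            n_split = length(bp$split_read_ids),
            n_spanning = length(bp$spanning_compatible_ids),
            est_spanning = ab$est_spanning[j],
            est_total = ab$est_total_fragments[j],
            counter_5p = bp$counter_5p_count, counter_3p = bp$counter_3p_count,
            splice_type = agree$splice_type,
            consensus = agree$consensus,
            ref_agree = agree$left_ref_agree && agree$right_ref_agree,
            ffpm = ffpm(est, total_fragments),
            far_5p = fusion_allelic_ratio(est, bp$counter_5p_count),
            far_3p = fusion_allelic_ratio(est, bp$counter_3p_count),
            counter_ffpm_5p = ffpm(bp$counter_5p_count, total_fragments),
            counter_ffpm_3p = ffpm(bp$counter_3p_count, total_fragments),
            n_microhomologies = nrow(mh$matches),
            microhomology_distance = microhomology_distance(bp, mh, contig),
            filter_status = if (dec$passed) "PASS" else
              paste(dec$failed_rules, collapse = ";"),
            stringsAsFactors = FALSE)
        })
        list(rows = do.call(rbind, vrows))
      }
    }, error = function(e) {
      if (grepl("unknown gene|ambiguous locus|self-fusion", conditionMessage(e))) {
        list(unresolvable = conditionMessage(e))
      } else stop(e)
    })
    if (!is.null(res$unresolvable)) {
      status[fusion_name] <- "unresolvable"
    } else if (!is.null(res$rows)) {
      rows[[fusion_name]] <- res$rows
    }
  }

  report <- if (length(rows)) do.call(rbind, rows) else empty_report()
  rownames(report) <- NULL

  if (nrow(report) > 0) {
    # sample-level promiscuity / paralog screens on min-evidence survivors
    surv <- report[report$filter_status == "PASS", , drop = FALSE]
    fus <- unique(surv[, c("gene_a", "gene_b")])
    if (nrow(fus) > 0) {
      fus$support <- vapply(seq_len(nrow(fus)), function(i) {
        sum(surv$est_total[surv$gene_a == fus$gene_a[i] &
                             surv$gene_b == fus$gene_b[i]])
      }, numeric(1))
      prom <- promiscuity_filter(fus, cfg$max_partners)
      para <- if (!is.null(cfg$paralogs)) {
        paralog_filter(fus, read_paralog_pairs(cfg$paralogs))
      } else NULL
      for (i in seq_len(nrow(fus))) {
        failed <- prom[[i]]$failed_rules
        if (!is.null(para)) failed <- c(failed, para[[i]]$failed_rules)
        if (length(failed) > 0) {
          hit <- report$gene_a == fus$gene_a[i] & report$gene_b == fus$gene_b[i] &
            report$filter_status == "PASS"
          report$filter_status[hit] <- paste(failed, collapse = ";")
        }
      }
    }
  }

  if (!is.null(cfg$model) && nrow(report) > 1) {
    feats <- as.matrix(report[, FEATURE_NAMES[FEATURE_NAMES %in% names(report)]])
    raw <- cbind(ffpm = report$ffpm, far_5p = report$far_5p,
                 far_3p = report$far_3p,
                 counter_ffpm_5p = report$counter_ffpm_5p,
                 counter_ffpm_3p = report$counter_ffpm_3p,
                 consensus_indicator = as.numeric(report$consensus),
                 ref_agree_indicator = as.numeric(report$ref_agree),
                 n_microhomologies = report$n_microhomologies,
                 microhomology_distance = report$microhomology_distance)
    pred <- predict_category(cfg$model, scale_features(raw))
    report$cluster <- pred$cluster
    report$category <- pred$category
  } else {
    report$cluster <- rep(NA_character_, nrow(report))
    report$category <- rep(NA_character_, nrow(report))
  }

  passed <- report[report$filter_status == "PASS", , drop = FALSE]
  filtered <- report[report$filter_status != "PASS", , drop = FALSE]
  for (fn in unique(report$fusion)) {
    sub <- report[report$fusion == fn, , drop = FALSE]
    status[fn] <- if (any(sub$filter_status == "PASS")) "validated" else
      paste0("filtered:", paste(sort(unique(unlist(
        strsplit(sub$filter_status, ";", fixed = TRUE)))), collapse = ";"))
  }

  out <- list(report = passed, filtered = filtered, all_variants = report,
              summary = as.list(status), total_fragments = total_fragments,
              seed = cfg$seed)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    report_path <- file.path(cfg$out_dir, "fusions.report.tsv")
    filtered_path <- file.path(cfg$out_dir, "fusions.filtered.tsv")
    summary_path <- file.path(cfg$out_dir, "summary.json")
    write_report(passed, report_path)
    write_report(filtered, filtered_path)
    jsonlite::write_json(
      list(status = as.list(status), total_fragments = total_fragments,
           seed = cfg$seed, n_validated_variants = nrow(passed)),
      summary_path, auto_unbox = TRUE, pretty = TRUE)
    out$report_path <- report_path
    out$filtered_path <- filtered_path
    out$summary_path <- summary_path
  }
  out
}

empty_report <- function() {
  data.frame(fusion = character(0), contig = character(0),
             gene_a = character(0), gene_b = character(0),
             left_break = integer(0), right_break = integer(0),
             left_chrom = character(0), left_genome = integer(0),
             left_strand = character(0), right_chrom = character(0),
             right_genome = integer(0), right_strand = character(0),
             n_split = integer(0), n_spanning = integer(0),
             est_spanning = numeric(0), est_total = numeric(0),
             counter_5p = integer(0), counter_3p = integer(0),
             splice_type = character(0), consensus = logical(0),
             ref_agree = logical(0), ffpm = numeric(0), far_5p = numeric(0),
             far_3p = numeric(0), counter_ffpm_5p = numeric(0),
             counter_ffpm_3p = numeric(0), n_microhomologies = integer(0),
             microhomology_distance = numeric(0),
             filter_status = character(0), stringsAsFactors = FALSE)
}

#' Write a variant report as TSV (numeric fields at 4 decimals)
#'
#' @param report Report data.frame from [run_inspect()].
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  fmt <- report
  num <- vapply(fmt, is.numeric, logical(1)) &
    !vapply(fmt, is.integer, logical(1))
  for (cn in names(fmt)[num]) fmt[[cn]] <- sprintf("%.4f", fmt[[cn]])
  write.table(fmt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Tag report rows against named gene/fusion sets
#'
#' Adds one boolean column per tag list (e.g. known-fusion membership or
#' exclusion lists) without removing any rows; entries containing `::` or
#' `--` match the fusion name, bare identifiers match either partner gene.
#'
#' @param rows Report data.frame (needs `fusion`, `gene_a`, `gene_b`).
#' @param tag_lists Named list of character vectors.
#' @return The report with one `tag_<name>` logical column per list.
#' @export
annotate_report <- function(rows, tag_lists) {
  for (nm in names(tag_lists)) {
    vals <- tag_lists[[nm]]
    vals_norm <- gsub("--", "::", vals, fixed = TRUE)
    is_fusion <- grepl("::", vals_norm, fixed = TRUE)
    hit <- rows$fusion %in% vals_norm[is_fusion] |
      rows$gene_a %in% vals_norm[!is_fusion] |
      rows$gene_b %in% vals_norm[!is_fusion]
    rows[[paste0("tag_", nm)]] <- hit
  }
  rows
}
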
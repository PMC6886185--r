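# Pipeline orchestration: a single config object carrying every threshold
# the analyses use, a run_pipeline() driver executing the stages in
# dependency order with a manifest, and a small subcommand-style CLI.

#' Build a pipeline configuration
#'
#' Every analysis threshold is a named key with its conventional default:
#' RIP and shift FDR 0.05, P-site offset 13, footprint lengths 28-30 with
#' modal-frame periodicity threshold 0.6, metagene filters (>= 25
#' footprints, CDS > 300 nt), 5'UTR length > 100 nt, 50-nt UTR windows, 75
#' metagene codons, 6-nt GC window. Correction methods default to
#' Bonferroni for motif/score comparisons and BH for the knockdown-shift
#' comparison, matching the respective analyses.
#'
#' @param input_dir directory holding the input files (the layout written
#'   by [simulate_dataset()]).
#' @param out_dir output directory.
#' @param ... overrides for any default listed above.
#' @param seed RNG seed recorded in the manifest.
#' @return a `ribofate_config` list.
#' @export
pipeline_config <- function(input_dir, out_dir, ..., seed = 1) {
  cfg <- list(
    input_dir = input_dir, out_dir = out_dir, seed = seed,
    rip_fdr = 0.05, shift_fdr = 0.05, periodicity = 0.6, offset = 13,
    rpf_lengths = 28:30, min_rpf = 25, min_cds = 301, min_utr5 = 101,
    gc_window = 6, metagene_codons = 75, utr_window = 50,
    correction_scores = "bonferroni", correction_shift = "benjamini_hochberg",
    correction_motifs = "bonferroni", pct_threshold = 0.5
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  num <- c("rip_fdr", "shift_fdr", "periodicity", "offset", "min_rpf",
           "min_cds", "min_utr5", "gc_window", "metagene_codons",
           "utr_window")
  bad <- vapply(cfg[num], function(v) !is.numeric(v) || v <= 0, logical(1))
  if (any(bad)) stop("thresholds must be positive: ",
                     paste(num[bad], collapse = ", "))
  for (k in grep("^correction_", names(cfg), value = TRUE)) {
    if (!cfg[[k]] %in% c("bonferroni", "benjamini_hochberg")) {
      stop(k, " must be bonferroni or benjamini_hochberg")
    }
  }
  structure(cfg, class = c("ribofate_config", "list"))
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with `input_dir`, `out_dir` and optional
#'   threshold overrides (keys as in [pipeline_config()]).
#' @return a `ribofate_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$input_dir) || is.null(y$out_dir)) {
    stop("config must set input_dir and out_dir")
  }
  do.call(pipeline_config, y)
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full pipeline
#'
#' Stages in dependency order: input reading -> RIP enrichment and binding
#' partition -> polysome association and knockdown shifts -> ribosome
#' occupancy (metagene, 5'UTR) -> sequence features -> initiation-site and
#' miRNA-family analyses -> binding-curve fits. Each stage writes TSV/JSON
#' outputs under `out_dir`; a failing stage leaves a `FAILED_<stage>`
#' marker and does not corrupt the outputs of other stages. A manifest
#' lists every output with md5 checksum, the seed and per-stage row counts.
#'
#' @param config a `ribofate_config`.
#' @return (invisibly) named list of per-stage results (`NULL` for failed
#'   stages, error message in `errors`).
#' @export
run_pipeline <- function(config) {
  cfg <- config
  req <- c("transcripts.fa", "regions.tsv", "total_counts.tsv",
           "total_meta.tsv")
  missing <- req[!file.exists(file.path(cfg$input_dir, req))]
  if (length(missing)) {
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  inp <- function(f) file.path(cfg$input_dir, f)
  outp <- function(f) file.path(cfg$out_dir, f)
  results <- list()
  errors <- list()
  counts_of <- list()
  run_stage <- function(name, fun) {
    r <- tryCatch(fun(), error = function(e) {
      writeLines(conditionMessage(e), outp(paste0("FAILED_", name)))
      errors[[name]] <<- conditionMessage(e)
      stage_log(name, "FAILED: ", conditionMessage(e))
      NULL
    })
    results[[name]] <<- r
    r
  }

  tx <- read_transcriptome(inp("transcripts.fa"), inp("regions.tsv"))
  stage_log("io", nrow(tx), " transcripts read")
  counts_of$transcripts <- nrow(tx)

  run_stage("rip", function() {
    files <- list.files(cfg$input_dir, "^rip_.*_counts\\.tsv$")
    if (!length(files)) stop("no RIP count files")
    proteins <- sub("^rip_(.*)_counts\\.tsv$", "\\1", files)
    rip <- lapply(setNames(proteins, proteins), function(pr) {
      cm <- read_counts(inp(sprintf("rip_%s_counts.tsv", pr)),
                        inp(sprintf("rip_%s_meta.tsv", pr)))
      ipc <- cm$sample_meta$assay == "rip_ip"
      res <- enrichment_test(cm$counts[, ipc, drop = FALSE],
                             cm$counts[, !ipc, drop = FALSE],
                             cm$library_sizes[ipc],
                             cm$library_sizes[!ipc],
                             fdr_threshold = cfg$rip_fdr)
      write_tsv(res, outp(sprintf("rip_%s.tsv", pr)))
      res
    })
    partition <- assign_binding_groups(rip, cfg$rip_fdr)
    write_tsv(partition, outp("binding_groups.tsv"))
    stage_log("rip", nrow(partition), " genes partitioned")
    list(rip = rip, partition = partition)
  })

  run_stage("polysome", function() {
    conds <- sub("^gradient_(.*)_counts\\.tsv$", "\\1",
                 list.files(cfg$input_dir, "^gradient_.*_counts\\.tsv$"))
    if (!length(conds)) stop("no gradient count files")
    cms <- lapply(setNames(nm = conds), function(cd) {
      read_counts(inp(sprintf("gradient_%s_counts.tsv", cd)),
                  inp(sprintf("gradient_%s_meta.tsv", cd)))
    })
    scores <- lapply(cms, association_score)
    for (cd in conds) {
      write_tsv(scores[[cd]], outp(sprintf("association_%s.tsv", cd)))
    }
    out <- list(scores = scores)
    if (all(c("control", "cnot1_kd") %in% conds)) {
      shifts <- differential_shift(cms$control, cms$cnot1_kd,
                                   cfg$shift_fdr)
      write_tsv(shifts, outp("shifts.tsv"))
      delta <- setNames(scores$cnot1_kd$score - scores$control$score,
                        scores$control$gene_id)
      out$shifts <- shifts
      out$delta_score <- delta
      if (!is.null(results$rip)) {
        cmp <- group_shift_comparison(delta, results$rip$partition,
                                      correction = cfg$correction_shift)
        write_tsv(cmp, outp("shift_group_tests.tsv"))
        out$group_tests <- cmp
      }
    }
    stage_log("polysome", length(scores$control$gene_id) %||% 0L,
              " genes scored")
    out
  })

  run_stage("ribo", function() {
    if (!file.exists(inp("rpf_reads.tsv"))) stop("no footprint file")
    reads <- read_read_positions(inp("rpf_reads.tsv"))
    tot <- read.delim(inp("rpf_total_counts.tsv"),
                      stringsAsFactors = FALSE)
    ds <- rpf_dataset(reads, tx, setNames(tot$count, tot$transcript_id),
                      offset = cfg$offset, lengths = cfg$rpf_lengths,
                      threshold = cfg$periodicity)
    groups <- split(tx$transcript_id,
                    partition_label_for_tx(tx, results$rip$partition))
    meta <- lapply(groups, function(ids) {
      tryCatch(metagene_cds(ds, tx, ids, cfg$metagene_codons,
                            cfg$min_rpf, cfg$min_cds),
               error = function(e) NULL)
    })
    u5 <- lapply(groups, function(ids) {
      tryCatch(utr5_occupancy(ds, tx, ids, cfg$utr_window, cfg$min_utr5),
               error = function(e) NULL)
    })
    mg_tab <- do.call(rbind, lapply(names(meta), function(g) {
      m <- meta[[g]]
      if (is.null(m)) return(NULL)
      data.frame(group = g, position = c(names(m$start_profile),
                                         names(m$stop_profile)),
                 occupancy = c(m$start_profile, m$stop_profile),
                 stringsAsFactors = FALSE)
    }))
    if (!is.null(mg_tab)) write_tsv(mg_tab, outp("metagene.tsv"))
    u5_tab <- do.call(rbind, lapply(names(u5), function(g) {
      d <- u5[[g]]
      if (is.null(d)) return(NULL)
      cbind(group = g, d)
    }))
    if (!is.null(u5_tab)) write_tsv(u5_tab, outp("utr5_occupancy.tsv"))
    stage_log("ribo", length(ds$occupancy), " transcripts with occupancy")
    list(dataset = ds, metagene = meta, utr5 = u5)
  })

  run_stage("seqfeat", function() {
    lab <- partition_label_for_tx(tx, results$rip$partition)
    freq5 <- vapply(tx$utr5, motif_frequency, numeric(1), USE.NAMES = FALSE)
    feats <- data.frame(
      transcript_id = tx$transcript_id, group = lab,
      utr5_motif_freq = freq5,
      cds_motif_freq = vapply(tx$cds, motif_frequency, numeric(1),
                              USE.NAMES = FALSE),
      utr3_motif_freq = vapply(tx$utr3, motif_frequency, numeric(1),
                               USE.NAMES = FALSE),
      pumilio_sites = vapply(tx$utr3, pumilio_sites, integer(1),
                             USE.NAMES = FALSE),
      stringsAsFactors = FALSE
    )
    write_tsv(feats, outp("sequence_features.tsv"))
    cmp <- group_motif_comparison(
      split(feats$utr5_motif_freq, feats$group),
      correction = cfg$correction_motifs)
    write_tsv(cmp$tests, outp("motif_group_tests.tsv"))
    profs <- lapply(c(first = "utr5_first50", last = "utr5_last50"),
                    function(rg) {
      lapply(split(tx$utr5, lab), function(s) {
        tryCatch(positional_profile(s, tx$utr5, rg, width = cfg$utr_window),
                 error = function(e) NULL)
      })
    })
    stage_log("seqfeat", nrow(feats), " transcripts profiled")
    list(features = feats, tests = cmp, profiles = profs)
  })

  run_stage("tis", function() {
    if (!file.exists(inp("initiation_peaks.tsv"))) stop("no peak file")
    peaks <- read_initiation_peaks(inp("initiation_peaks.tsv"))
    cls <- classify_tis_table(peaks)
    write_tsv(cls, outp("tis_classification.tsv"))
    part_tx <- data.frame(
      transcript_id = tx$transcript_id,
      label = partition_label_for_tx(tx, results$rip$partition),
      stringsAsFactors = FALSE)
    props <- group_tis_proportions(cls, part_tx)
    write_tsv(props, outp("tis_proportions.tsv"))
    out <- list(classification = cls, proportions = props)
    if (file.exists(inp("mirna_families.tsv"))) {
      fam <- read_mirna_families(inp("mirna_families.tsv"),
                                 cfg$pct_threshold)
      groups <- split(results$rip$partition$gene_id,
                      results$rip$partition$label)
      if (file.exists(inp("reference_targets.tsv"))) {
        ref <- read.delim(inp("reference_targets.tsv"),
                          stringsAsFactors = FALSE)$gene_id
        groups$tnrc6_up <- ref
      }
      enr <- mirna_family_enrichment(groups, fam,
                                     results$rip$partition$gene_id)
      write_tsv(enr, outp("mirna_enrichment.tsv"))
      out$mirna <- enr
    }
    stage_log("tis", nrow(cls), " transcripts classified")
    out
  })

  run_stage("binding", function() {
    if (!file.exists(inp("binding_titration.tsv"))) stop("no binding data")
    tit <- read.delim(inp("binding_titration.tsv"),
                      stringsAsFactors = FALSE)
    fits <- lapply(split(tit, paste(tit$protein, tit$rna, sep = "_")),
                   function(d) {
                     dy <- anisotropy_change(d$conc_M, d$signal)
                     fit_hill(d$conc_M, dy)
                   })
    kin <- read.delim(inp("binding_kinetics.tsv"),
                      stringsAsFactors = FALSE)
    dfits <- lapply(split(kin, paste(kin$protein, kin$rna, sep = "_")),
                    function(d) fit_exp_decay(d$time_min, d$signal))
    tidy <- function(fl, model) {
      do.call(rbind, lapply(names(fl), function(id) {
        f <- fl[[id]]
        data.frame(id = id, model = model, t(f$params),
                   converged = f$converged, stringsAsFactors = FALSE)
      }))
    }
    jsonlite::write_json(
      list(hill = lapply(fits, unclass), decay = lapply(dfits, unclass)),
      outp("binding_fits.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    write_tsv(tidy(fits, "hill"), outp("binding_hill.tsv"))
    write_tsv(tidy(dfits, "exp_decay"), outp("binding_decay.tsv"))
    stage_log("binding", length(fits), " titrations fit")
    list(hill = fits, decay = dfits)
  })

  out_files <- setdiff(list.files(cfg$out_dir), "manifest.json")
  manifest <- list(
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("ribofate")),
    config = unclass(cfg),
    stage_counts = counts_of,
    failed_stages = names(errors),
    outputs = lapply(setNames(nm = out_files), function(f) {
      list(md5 = unname(tools::md5sum(outp(f))),
           bytes = file.size(outp(f)))
    })
  )
  jsonlite::write_json(manifest, outp("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  results$errors <- errors
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Map transcript ids to binding-group labels through their genes; "none"
# when no partition is available.
partition_label_for_tx <- function(tx, partition) {
  if (is.null(partition)) return(rep("none", nrow(tx)))
  lab <- setNames(partition$label, partition$gene_id)[tx$gene_id]
  lab[is.na(lab)] <- "none"
  unname(lab)
}

#' Command-line interface
#'
#' Subcommand dispatcher: `simulate --preset paperlike --seed 1 --out dir`,
#' `run --config config.yaml`, `rip --counts c.tsv --meta m.tsv --fdr 0.05
#' --out rip.tsv`, `binding fit-hill|fit-decay --in data.tsv --out
#' fit.json`. Invoke via `Rscript -e 'ribofate::ribofate_cli()' <args>` or
#' the launcher in `inst/cli/ribofate.R`.
#'
#' @param args character vector (default: command-line arguments).
#' @return exit status, invisibly.
#' @export
ribofate_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    message("usage: ribofate <simulate|run|rip|binding> [options]")
    return(invisible(1L))
  }
  cmd <- args[1]
  opts <- if (cmd == "binding") list() else parse_cli_opts(args[-1])
  switch(cmd,
    simulate = {
      simulate_dataset(opts$out %||% ".",
                       preset = opts$preset %||% "paperlike",
                       seed = as.integer(opts$seed %||% 1))
    },
    run = {
      run_pipeline(read_config(opts$config))
    },
    rip = {
      cm <- read_counts(opts$counts, opts$meta)
      ipc <- cm$sample_meta$assay == "rip_ip"
      res <- enrichment_test(cm$counts[, ipc, drop = FALSE],
                             cm$counts[, !ipc, drop = FALSE],
                             cm$library_sizes[ipc], cm$library_sizes[!ipc],
                             as.numeric(opts$fdr %||% 0.05))
      write_tsv(res, opts$out)
    },
    binding = {
      sub <- args[2]
      opts <- parse_cli_opts(args[-(1:2)])
      d <- read.delim(opts[["in"]], stringsAsFactors = FALSE)
      fit <- switch(sub,
        `fit-hill` = fit_hill(d$conc_M,
                              anisotropy_change(d$conc_M, d$signal)),
        `fit-decay` = fit_exp_decay(d$time_min, d$signal),
        `fit-competition` = fit_competition(d$conc_M, d$fraction_bound),
        stop("unknown binding subcommand: ", sub))
      jsonlite::write_json(unclass(fit), opts$out, auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
    },
    stop("unknown subcommand: ", cmd)
  )
  invisible(0L)
}

parse_cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    if (!startsWith(args[i], "--")) stop("expected --option, got ", args[i])
    key <- substring(args[i], 3)
    if (i == length(args) || startsWith(args[i + 1], "--")) {
      opts[[key]] <- TRUE
      i <- i + 1L
    } else {
      opts[[key]] <- args[i + 1]
      i <- i + 2L
    }
  }
  opts
}
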
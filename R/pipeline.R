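#' Pipeline configuration
#'
#' Aggregates every stage's parameters with the study-style defaults
#' (trim 20/20/4:20/30/30, consensus minimum depth 2, 3x-breadth gate
#' 0.80, missing-data filter 0.10, damage window 25, network epsilon 0)
#' plus the synthetic-data block driving desk-scale runs.
#'
#' @param seed global seed; per-stage seeds are derived from it.
#' @param outdir output directory for intermediate files and the report
#'   (`NULL` = keep everything in memory).
#' @param stages character vector of stages to run, in order, from
#'   `c("simulate","trim","map","dedup","damage","consensus","diagnose",
#'   "assign","network")`.
#' @param panel a [panel_config()] for the simulated clade panel.
#' @param reads a [read_sim_params()] for endogenous reads.
#' @param query_clade clade the simulated query individual belongs to.
#' @param contamination_fraction contaminant read fraction (contaminant
#'   drawn from another clade).
#' @param contaminant_clade clade contaminant reads are simulated from
#'   (default: the lexicographically first non-query clade).
#' @param trim a [trim_config()].
#' @param map a [map_params()].
#' @param min_depth,breadth3_min consensus/QC thresholds.
#' @param max_missing_frac missing-data threshold for site discovery and
#'   region filtering.
#' @param damage_positions terminal window for the damage profile.
#' @param network_region 0-based half-open column interval for the
#'   haplotype-network sub-alignment (`NULL` = whole alignment).
#' @param epsilon median-joining slack.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, outdir = NULL,
                            stages = c(
                              "simulate", "trim", "map", "dedup", "damage",
                              "consensus", "diagnose", "assign", "network"
                            ),
                            panel = panel_config(seed = derive_seed(seed, "panel")),
                            reads = read_sim_params(seed = derive_seed(seed, "reads")),
                            query_clade = "cladeB",
                            contamination_fraction = 0,
                            contaminant_clade = NULL,
                            trim = trim_config(),
                            map = map_params(),
                            min_depth = 2L, breadth3_min = 0.80,
                            max_missing_frac = 0.10,
                            damage_positions = 25L,
                            network_region = NULL, epsilon = 0) {
  known <- c(
    "simulate", "trim", "map", "dedup", "damage", "consensus",
    "diagnose", "assign", "network"
  )
  if (!all(stages %in% known)) stop("unknown stage name", call. = FALSE)
  structure(
    list(
      seed = as.integer(seed), outdir = outdir, stages = stages,
      panel = panel, reads = reads, query_clade = query_clade,
      contamination_fraction = contamination_fraction,
      contaminant_clade = contaminant_clade,
      trim = trim, map = map, min_depth = as.integer(min_depth),
      breadth3_min = breadth3_min, max_missing_frac = max_missing_frac,
      damage_positions = as.integer(damage_positions),
      network_region = network_region, epsilon = epsilon
    ),
    class = "pipeline_config"
  )
}

.log_stage <- function(verbose, stage, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the end-to-end desk-scale pipeline
#'
#' Simulates a clade panel and ancient reads for a query individual
#' (optionally admixed with contaminant reads from another clade), then
#' trims, maps against every clade reference selecting the best, removes
#' duplicates, profiles damage, calls the consensus with QC, discovers
#' diagnostic sites, measures per-site read agreement, assigns the query
#' to a clade, and builds haplotype networks. Any stage failure halts with
#' the stage name; the partial report is attached to the error condition.
#'
#' @param config a [pipeline_config()].
#' @param verbose emit one log line per stage.
#' @return a `pipeline_report` list of per-stage summaries plus
#'   provenance (`seed`, `config_hash`, package version).
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- list(
    provenance = list(
      package = "paleomito",
      version = as.character(utils::packageVersion("paleomito")),
      seed = config$seed,
      config_hash = config_hash(config)
    )
  )
  state <- list()
  halt <- function(stage, e) {
    cond <- structure(
      class = c("pipeline_error", "error", "condition"),
      list(
        message = sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
        call = NULL, stage = stage, partial_report = report
      )
    )
    stop(cond)
  }
  for (stage in config$stages) {
    res <- tryCatch(
      .run_stage(stage, config, state, verbose),
      error = function(e) halt(stage, e)
    )
    state <- res$state
    report[[stage]] <- res$summary
  }
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    .write_outputs(config, state, report)
  }
  class(report) <- "pipeline_report"
  report
}

.run_stage <- function(stage, config, state, verbose) {
  switch(stage,
    simulate = {
      sim <- simulate_panel(config$panel)
      clades <- sort(unique(sim$panel$labels$clade))
      if (!config$query_clade %in% clades) {
        stop("query_clade not in simulated panel")
      }
      ## the query individual: a panel-style private-variant carrier of the
      ## query clade, sequenced as ancient reads
      query_genome <- sim$references[[config$query_clade]]
      reads <- simulate_reads(query_genome, config$reads, label = "endo")
      if (config$contamination_fraction > 0) {
        cclade <- config$contaminant_clade %||%
          setdiff(clades, config$query_clade)[1]
        cparams <- config$reads
        cparams$seed <- derive_seed(config$seed, "contaminant")
        creads <- simulate_reads(
          sim$references[[cclade]], cparams,
          label = "cont"
        )
        reads <- mix_contamination(
          reads, creads, config$contamination_fraction,
          seed = derive_seed(config$seed, "mix")
        )
      }
      state$panel <- sim$panel
      state$references <- sim$references
      state$sim <- reads
      state$reads <- reads$reads
      .log_stage(
        verbose, stage, "%d clades, %d reads", length(clades),
        nrow(reads$reads)
      )
      list(state = state, summary = list(
        n_clades = length(clades), n_samples = length(sim$panel$seqs),
        n_reads = nrow(reads$reads),
        contamination_fraction = config$contamination_fraction
      ))
    },
    trim = {
      tr <- trim_set(state$reads, config$trim)
      state$reads <- tr$reads
      .log_stage(
        verbose, stage, "%d -> %d reads", tr$stats$n_in,
        tr$stats$n_kept
      )
      list(state = state, summary = unclass(tr$stats))
    },
    map = {
      sel <- select_best_reference(state$reads, state$references, config$map)
      state$mapped <- sel$alignments
      state$best_ref <- sel$best_ref
      state$ref_seq <- state$references[[sel$best_ref]]
      .log_stage(
        verbose, stage, "best ref %s, %d reads retained", sel$best_ref,
        nrow(sel$alignments)
      )
      list(state = state, summary = list(
        best_ref = sel$best_ref, tie = sel$tie, table = sel$table
      ))
    },
    dedup = {
      dd <- deduplicate(state$mapped)
      state$mapped <- dd$reads
      .log_stage(
        verbose, stage, "duplication level %.3f",
        dd$stats$duplication_level
      )
      list(state = state, summary = dd$stats)
    },
    damage = {
      dp <- damage_profile(state$mapped, state$ref_seq, config$damage_positions)
      state$damage <- dp
      .log_stage(
        verbose, stage, "5' C>T %.4f, 3' G>A %.4f",
        dp$freq5[1, "C>T"], dp$freq3[1, "G>A"]
      )
      list(state = state, summary = list(
        ct_5p_offset0 = unname(dp$freq5[1, "C>T"]),
        ga_3p_offset0 = unname(dp$freq3[1, "G>A"])
      ))
    },
    consensus = {
      pl <- make_pileup(state$mapped, nchar(state$ref_seq))
      cons <- call_consensus(pl, config$min_depth)
      qc <- qc_retain(cons, config$breadth3_min)
      state$pileup <- pl
      state$consensus <- cons
      .log_stage(
        verbose, stage, "mean depth %.1fx, breadth3 %.3f, retained %s",
        cons$stats$mean_depth, cons$stats$breadth[3], qc$retained
      )
      list(state = state, summary = list(
        mean_depth = cons$stats$mean_depth,
        breadth = as.list(cons$stats$breadth),
        undetermined_fraction = cons$stats$undetermined_fraction,
        gc_content = tryCatch(gc_content(cons$seq), error = function(e) NA),
        retained = qc$retained, reasons = qc$reasons
      ))
    },
    diagnose = {
      sites <- find_inter_clade_fixed_sites(
        state$panel, config$max_missing_frac,
        focal_clade = config$query_clade
      )
      ag <- site_agreement(state$pileup, sites)
      sites2 <- find_clade_fixed_query_divergent_sites(
        state$panel, config$query_clade, state$consensus$seq
      )
      ag2 <- if (nrow(sites2)) site_agreement(state$pileup, sites2) else NULL
      state$sites <- sites
      state$agreement <- ag
      .log_stage(
        verbose, stage, "%d inter-clade sites, median agreement %.3f",
        nrow(sites), ag$median
      )
      list(state = state, summary = list(
        n_inter_clade_sites = nrow(sites),
        agreement_median = ag$median, agreement_iqr = ag$iqr,
        n_query_divergent_sites = nrow(sites2),
        query_divergent_agreement_median = if (is.null(ag2)) NA else ag2$median
      ))
    },
    assign = {
      asn <- assign_clade(state$consensus$seq, state$panel, state$sites)
      state$assignment <- asn
      .log_stage(verbose, stage, "assigned %s", asn$assigned)
      list(state = state, summary = list(
        assigned = asn$assigned, votes = as.list(asn$votes),
        rule = asn$rule, n_usable_sites = asn$n_usable_sites
      ))
    },
    network = {
      aln <- c(state$panel$seqs, query = state$consensus$seq)
      if (!is.null(config$network_region)) {
        aln <- extract_region(aln, config$network_region)
      }
      aln <- filter_missing(aln, config$max_missing_frac)
      haps <- collapse_haplotypes(aln)
      net <- if (length(haps$seqs) >= 2L) {
        median_joining(haps, config$epsilon)
      } else {
        NULL
      }
      state$haplotypes <- haps
      state$network <- net
      .log_stage(
        verbose, stage, "%d haplotypes, %d nodes", length(haps$seqs),
        if (is.null(net)) 1L else nrow(net$nodes)
      )
      list(state = state, summary = list(
        n_haplotypes = length(haps$seqs),
        n_nodes = if (is.null(net)) 1L else nrow(net$nodes),
        n_median_nodes = if (is.null(net)) {
          0L
        } else {
          sum(net$nodes$type == "median")
        },
        total_cost = if (is.null(net)) 0L else sum(net$edges$weight)
      ))
    },
    stop("unknown stage: ", stage)
  )
}

.write_outputs <- function(config, state, report) {
  od <- config$outdir
  if (!is.null(state$reads)) {
    write_fastq(state$reads, file.path(od, "reads.fastq"))
  }
  if (!is.null(state$panel)) {
    write_clade_panel(
      state$panel, file.path(od, "panel.fasta"),
      file.path(od, "panel.tsv")
    )
  }
  if (!is.null(state$mapped) && !is.null(state$ref_seq)) {
    write_sam(state$mapped, file.path(od, "mapped.sam"), nchar(state$ref_seq))
  }
  if (!is.null(state$consensus)) {
    write_fasta(
      setNames(state$consensus$seq, "consensus"),
      file.path(od, "consensus.fasta")
    )
  }
  if (!is.null(state$damage)) {
    write.table(as.data.frame(state$damage), file.path(od, "damage.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  if (!is.null(state$network)) {
    write_network(
      state$network, file.path(od, "network_edges.tsv"),
      file.path(od, "network_nodes.tsv"), state$haplotypes
    )
  }
  write_report(report, file.path(od, "report.json"))
  invisible(od)
}

#' Stable hash of a pipeline configuration
#'
#' @param config a [pipeline_config()].
#' @return character hash.
#' @export
config_hash <- function(config) {
  rlang::hash(unclass(config))
}

#' Serialize a pipeline report to JSON
#'
#' @param report a `pipeline_report`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_report <- function(report, file) {
  jsonlite::write_json(unclass(report), file,
    auto_unbox = TRUE, digits = NA,
    pretty = TRUE, force = TRUE
  )
  invisible(file)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report\n")
  for (nm in setdiff(names(x), "provenance")) {
    cat(sprintf("  %s:\n", nm))
    s <- x[[nm]]
    for (k in names(s)) {
      v <- s[[k]]
      if (is.data.frame(v) || length(v) > 6L) next
      cat(sprintf(
        "    %s: %s\n", k,
        paste(format(unlist(v), digits = 4), collapse = ", ")
      ))
    }
  }
  invisible(x)
}
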
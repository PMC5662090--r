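#' Run the barcoding evaluation pipeline from a config
#'
#' Orchestrates simulate (or load) -> distances -> identification ->
#' tree-based identification -> species discovery -> congruence, writing
#' every stage's table under `out_dir` and returning a manifest of outputs
#' with file digests. Deterministic stages reproduce identical outputs from
#' an identical config; stochastic stages (simulation, MCMC) are controlled
#' by the config seed.
#'
#' @param config Path to a YAML config, or an equivalent named list.
#'   Recognized fields: `out_dir`; `seed`; either `simulate` (arguments to
#'   [sim_config()]) or `inputs` (`alignment` FASTA path, optional `tree`
#'   Newick path with `support_type`); `marker` (which simulated marker to
#'   analyse, default `"ITS"`); `rank`; `identify` (`methods`, `threshold`
#'   percent or `optimize: true`); `tree_id` (`min_bootstrap`,
#'   `min_posterior`, `use`); `abgd` (arguments to [abgd_config()]); `ptp`
#'   (`method` `"ml"`/`"bayes"`, `iterations`, `sample_every`, `burnin`);
#'   `congruence` (logical).
#' @return A `run_manifest`: config, seed, stage outputs (paths and md5
#'   digests) and headline numbers per stage.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a YAML path or a list")
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config error: out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  rank <- if (is.null(config$rank)) "species" else config$rank
  if (!rank %in% c("species", "genus"))
    stop("config error: rank must be species or genus")
  idcfg <- config$identify
  methods <- if (is.null(idcfg$methods)) c("NN", "BCM", "TID")
             else toupper(unlist(idcfg$methods))
  optimize <- if (!is.null(idcfg$optimize)) isTRUE(idcfg$optimize)
              else is.null(idcfg$threshold)
  if (any(methods %in% c("BCM", "TID")) && !optimize &&
      is.null(idcfg$threshold))
    stop("config error: BCM/TID need a threshold or optimize: true")

  outputs <- list()
  numbers <- list()
  emit <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    outputs[[name]] <<- path
    path
  }
  tsv <- function(df, path) utils::write.table(df, path, sep = "\t",
                                               quote = FALSE, row.names = FALSE)

  # ---- inputs ----
  if (!is.null(config$simulate)) {
    simargs <- config$simulate
    simargs$seed <- seed
    sim <- simulate_library(do.call(sim_config, simargs))
    marker <- if (is.null(config$marker)) names(sim$alignments)[length(sim$alignments)]
              else config$marker
    if (!marker %in% names(sim$alignments))
      stop("config error: marker ", marker, " was not simulated")
    aln <- sim$alignments[[marker]]
    info_all <- sim$info
    tree <- sim$tree
    tree_use <- "bootstrap"
    for (mk in names(sim$alignments))
      emit(paste0("alignment_", mk, ".fasta"),
           function(p) write_alignment(sim$alignments[[mk]], p))
    emit("truth_tree.nwk", function(p) write_support_tree(sim$tree, p))
    emit("truth_partition.tsv", function(p) write_partition(sim$partition, p))
    emit("species_map.tsv", function(p) tsv(sim$info, p))
  } else if (!is.null(config$inputs)) {
    aln <- read_alignment(config$inputs$alignment)
    info_all <- aln$info
    tree <- NULL
    tree_use <- config$inputs$support_type
    if (!is.null(config$inputs$tree)) {
      if (is.null(tree_use))
        stop("config error: inputs$support_type required with inputs$tree")
      tree <- read_support_tree(config$inputs$tree, tree_use)
    }
  } else {
    stop("config error: need either simulate or inputs")
  }

  # ---- distances ----
  aln2 <- remove_singletons(aln, rank = "species")
  numbers$n_individuals <- length(aln2$seq)
  numbers$n_singletons_removed <- length(attr(aln2, "removed"))
  dm <- distance_matrix(aln2)
  numbers$n_masked_pairs <- length(dm$masked_pairs)
  emit("distance_matrix.tsv", function(p) write_distance_matrix(dm, p))
  summ <- summarize_distances(dm, aln2$info)
  emit("distance_summary.tsv", function(p) tsv(
    data.frame(genus = names(summ$per_genus),
               mean_intra = vapply(summ$per_genus, `[[`, 0, "mean_intra"),
               mean_inter = vapply(summ$per_genus, `[[`, 0, "mean_inter")), p))
  numbers$mean_intra_pct <- summ$mean_intra
  numbers$mean_inter_pct <- summ$mean_inter

  # ---- distance identification ----
  threshold <- idcfg$threshold
  if (optimize) {
    prof <- optimize_threshold(dm, aln2$info, rank)
    threshold <- prof$optimum
    emit("threshold_profile.tsv", function(p) tsv(prof$profile, p))
    numbers$optimal_threshold_pct <- prof$optimum
  }
  for (m in methods) {
    res <- identify_all(dm, aln2$info, rank, m,
                        threshold = if (m == "NN") NULL else threshold)
    emit(paste0("identify_", tolower(m), ".tsv"), function(p) tsv(res, p))
    st <- success_table(res)
    top <- if (m == "NN") "true" else "correct"
    numbers[[paste0(tolower(m), "_", top, "_pct")]] <-
      st$percent[st$category == top]
  }

  # ---- tree identification ----
  if (!is.null(tree)) {
    tcfg <- config$tree_id
    collapsed <- collapse_unsupported(
      tree,
      min_bootstrap = if (is.null(tcfg$min_bootstrap)) 65 else tcfg$min_bootstrap,
      min_posterior = if (is.null(tcfg$min_posterior)) 0.95 else tcfg$min_posterior,
      use = if (is.null(tcfg$use)) tree_use else tcfg$use)
    tres <- liberal_classify_all(collapsed, info_all, rank)
    emit("identify_tree.tsv", function(p) tsv(tres, p))
    numbers$tree_success_pct <- 100 * mean(tres$category == "success")
    emit("monophyly.tsv",
         function(p) tsv(monophyly_report(collapsed, info_all, rank), p))
  }

  # ---- species discovery ----
  acfg <- config$abgd
  abgd <- abgd_partition(dm, do.call(abgd_config,
    acfg[intersect(names(acfg), names(formals(abgd_config)))]))
  pick <- if (!is.null(numbers$optimal_threshold_pct))
    select_partition(abgd, numbers$optimal_threshold_pct)
  else abgd$partitions[[which.min(abs(abgd$priors - mean(abgd$priors)))]]
  emit("abgd_partition.tsv", function(p) write_partition(pick, p))
  emit("abgd_scan.tsv", function(p) tsv(
    data.frame(prior = abgd$priors, entities = abgd$n_entities), p))
  numbers$abgd_entities <- n_entities(pick)

  ptp_part <- NULL
  if (!is.null(tree)) {
    pcfg <- config$ptp
    set.seed(seed)
    if (identical(pcfg$method, "bayes")) {
      bay <- ptp_bayes(tree, ptp_mcmc_config(
        iterations = if (is.null(pcfg$iterations)) 1e6 else pcfg$iterations,
        sample_every = if (is.null(pcfg$sample_every)) 1000 else pcfg$sample_every,
        burnin_fraction = if (is.null(pcfg$burnin)) 0.25 else pcfg$burnin,
        seed = seed))
      ptp_part <- bay$map$partition
      emit("ptp_trace.tsv", function(p) tsv(bay$trace, p))
      emit("ptp_supports.tsv", function(p) tsv(bay$supports, p))
    } else {
      ptp_part <- ptp_ml(tree)$partition
    }
    emit("ptp_partition.tsv", function(p) write_partition(ptp_part, p))
    numbers$ptp_entities <- n_entities(ptp_part)
  }

  # ---- congruence ----
  if (!identical(config$congruence, FALSE)) {
    rec <- classify_congruence(pick, aln2$info)
    emit("congruence_abgd.tsv", function(p) tsv(rec, p))
    cs <- congruence_summary(rec)
    emit("congruence_abgd_summary.tsv", function(p) tsv(cs, p))
    numbers$congruent_pct <- cs$percent[cs$category == "+"]
  }

  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  manifest <- structure(list(
    config = config,
    config_digest = unname(tools::md5sum(cfg_path)),
    seed = seed,
    outputs = outputs,
    digests = vapply(unlist(outputs), function(p) unname(tools::md5sum(p)),
                     character(1)),
    numbers = numbers), class = "run_manifest")
  saveRDS_path <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(list(seed = seed, outputs = unname(unlist(outputs)),
                        digests = as.list(manifest$digests),
                        numbers = numbers), saveRDS_path)
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("run_manifest:", length(x$outputs), "outputs, seed", x$seed, "\n")
  for (nm in names(x$numbers))
    cat(sprintf("  %-28s %s\n", nm, format(x$numbers[[nm]], digits = 6)))
  invisible(x)
}
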
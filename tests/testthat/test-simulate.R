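test_that("simulation is byte-identical under a fixed seed", {
  cfg <- sim_config(n_genera = 2, species_per_genus = 3,
                    individuals_per_species = c(2, 4), seed = 5)
  a <- simulate_library(cfg)
  b <- simulate_library(cfg)
  expect_identical(a$alignments$ITS$seq, b$alignments$ITS$seq)
  expect_identical(ape::write.tree(a$tree$phy), ape::write.tree(b$tree$phy))
  c3 <- simulate_library(sim_config(n_genera = 2, species_per_genus = 3,
                                    individuals_per_species = c(2, 4),
                                    seed = 6))
  expect_false(identical(a$alignments$ITS$seq, c3$alignments$ITS$seq))
})

test_that("gap scenario realizes max intra below min inter", {
  sim <- simulate_library(sim_config(n_genera = 1, species_per_genus = 5,
                                     individuals_per_species = c(4, 4),
                                     seed = 23))
  dm <- distance_matrix(concatenate(sim$alignments))
  labels <- taxon_labels(sim$info, "species")[dm$ids]
  same <- outer(labels, labels, "==")[upper.tri(dm$d)]
  vals <- dm$d[upper.tri(dm$d)]
  expect_lt(max(vals[same], na.rm = TRUE), min(vals[!same], na.rm = TRUE))
})

test_that("realized divergences track the configured means", {
  # targets are defined on the most variable marker
  cfg <- sim_config(n_genera = 4, species_per_genus = 5,
                    individuals_per_species = c(3, 8),
                    marker_lengths = c(ITS = 600),
                    marker_rel_rate = c(ITS = 1), seed = 77)
  sim <- simulate_library(cfg)
  dm <- distance_matrix(sim$alignments$ITS)
  s <- summarize_distances(dm, sim$info, percent = FALSE)
  n_intra <- sum(vapply(s$per_genus, function(g) length(g$intra), 0))
  expect_gte(n_intra, 200)
  expect_lt(abs(s$mean_intra - cfg$intra_mean) / cfg$intra_mean, 0.15)
  expect_lt(abs(s$mean_inter - cfg$inter_mean) / cfg$inter_mean, 0.15)
})

test_that("the realized transition/transversion ratio matches kappa", {
  # a long single marker so the event count is large enough for the
  # law-of-large-numbers check
  cfg <- sim_config(n_genera = 3, species_per_genus = 5,
                    individuals_per_species = c(6, 10), kappa = 2,
                    marker_lengths = c(ITS = 20000),
                    marker_rel_rate = c(ITS = 1),
                    seed = 55)
  sim <- simulate_library(cfg)
  ev <- sim$events
  expect_gte(sum(ev), 10000)
  # under K80 the transition:transversion EVENT ratio is kappa/2
  realized_kappa <- 2 * ev[["ts"]] / ev[["tv"]]
  expect_lt(abs(realized_kappa - cfg$kappa[1]) / cfg$kappa[1], 0.15)
})

test_that("markers differ in variability and missingness shapes alignments", {
  cfg <- sim_config(n_genera = 2, species_per_genus = 4,
                    individuals_per_species = c(2, 5),
                    missing_marker_prob = 0.2, seed = 19)
  sim <- simulate_library(cfg)
  n_all <- nrow(sim$info)
  n_per_marker <- vapply(sim$alignments, function(a) length(a$seq), 0)
  expect_true(any(n_per_marker < n_all))
  # concatenation refills the dropped individuals with N blocks
  co <- concatenate(sim$alignments)
  missing_its <- setdiff(co$info$individual_id,
                         sim$alignments$ITS$info$individual_id)
  if (length(missing_its)) {
    block <- substr(co$seq[[missing_its[1]]],
                    co$length - cfg$marker_lengths[["ITS"]] + 1, co$length)
    expect_equal(block, strrep("N", cfg$marker_lengths[["ITS"]]))
  }
  # less variable markers yield smaller mean distances
  d_rbcl <- distance_matrix(sim$alignments$rbcL)
  d_its <- distance_matrix(sim$alignments$ITS)
  expect_lt(mean(d_rbcl$d[upper.tri(d_rbcl$d)], na.rm = TRUE),
            mean(d_its$d[upper.tri(d_its$d)], na.rm = TRUE))
})

test_that("ambiguity injection writes IUPAC codes treated as missing", {
  cfg <- sim_config(n_genera = 1, species_per_genus = 2,
                    individuals_per_species = c(3, 3),
                    ambiguity_rate = 0.02, missing_marker_prob = 0, seed = 3)
  sim <- simulate_library(cfg)
  chars <- unique(unlist(strsplit(sim$alignments$ITS$seq, "")))
  expect_gt(length(setdiff(chars, c("A", "C", "G", "T"))), 0)
  expect_true(all(chars %in% c("A", "C", "G", "T", "R", "Y", "S", "W",
                               "K", "M")))
})

test_that("gap scenarios admit a zero-error threshold and radiations do not", {
  for (seed in c(101, 102)) {
    gap <- simulate_library(sim_config(n_genera = 2, species_per_genus = 4,
                                       individuals_per_species = c(2, 6),
                                       scenario = "gap", seed = seed))
    aln <- remove_singletons(gap$alignments$ITS)
    prof <- optimize_threshold(distance_matrix(aln), aln$info, "species")
    expect_equal(min(prof$profile$cumulative), 0)
    rad <- simulate_library(sim_config(n_genera = 2, species_per_genus = 4,
                                       individuals_per_species = c(3, 6),
                                       scenario = "radiation", seed = seed))
    aln2 <- remove_singletons(rad$alignments$ITS)
    prof2 <- optimize_threshold(distance_matrix(aln2), aln2$info, "species")
    expect_gt(min(prof2$profile$cumulative), 0)
  }
})

test_that("two-rate trees expose their class structure", {
  pt <- simulate_ptp_tree(4, 26, rate_ratio = 10, lambda_between = 1,
                          seed = 47)
  phy <- pt$tree$phy
  expect_setequal(unlist(pt$partition$groups), phy$tip.label)
  # recover the class of each edge from the true partition
  roots <- vapply(pt$partition$groups, function(tips) {
    if (length(tips) == 1) match(tips, phy$tip.label)
    else ape::getMRCA(phy, tips)
  }, integer(1))
  cl <- barcodeval:::roots_to_classes(phy, roots)
  w <- phy$edge.length[cl == "W"]
  s <- phy$edge.length[cl == "S"]
  expect_gte(length(w), 100)
  expect_lt(abs(mean(w) - 1 / 10) / (1 / 10), 0.20)
  # degenerate ratio: a single rate class ties toward one entity
  pt1 <- simulate_ptp_tree(2, 3, rate_ratio = 1, seed = 2)
  expect_error(simulate_ptp_tree(0, 3, 10), "at least 1")
})
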
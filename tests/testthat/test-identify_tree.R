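test_that("collapse respects the inclusive support boundary", {
  st <- read_tree_text("(((a:1,b:1)64:1,c:2)65:1,d:3);", "bootstrap")
  col <- collapse_unsupported(st, min_bootstrap = 65)
  # the 64 node collapses, the 65 node stays
  expect_equal(col$phy$Nnode, st$phy$Nnode - 1)
  expect_true(65 %in% col$bootstrap)
  expect_false(64 %in% col$bootstrap)
  # fully supported tree is untouched
  st2 <- read_tree_text("((a:1,b:1)99:1,(c:1,d:1)80:1);", "bootstrap")
  col2 <- collapse_unsupported(st2, 65)
  expect_equal(col2$phy$Nnode, st2$phy$Nnode)
  # all nodes unsupported -> star tree
  st3 <- read_tree_text("(((a:1,b:1)10:1,c:2)20:1,d:3);", "bootstrap")
  col3 <- collapse_unsupported(st3, 65)
  expect_equal(col3$phy$Nnode, 1)
})

test_that("collapsing preserves root-to-tip path lengths", {
  st <- read_tree_text("(((a:1,b:2)30:3,c:2)70:1,d:3);", "bootstrap")
  col <- collapse_unsupported(st, 65)
  depth0 <- ape::node.depth.edgelength(st$phy)
  depth1 <- ape::node.depth.edgelength(col$phy)
  m0 <- setNames(depth0[seq_along(st$phy$tip.label)], st$phy$tip.label)
  m1 <- setNames(depth1[seq_along(col$phy$tip.label)], col$phy$tip.label)
  expect_equal(m1[names(m0)], m0, tolerance = 1e-9)
})

test_that("dual trees collapse by the declared support type", {
  st <- read_tree_text("(((a:1,b:1)90/0.50:1,c:2)95/0.99:1,d:3);", "dual")
  expect_error(collapse_unsupported(st), "which support")
  by_bs <- collapse_unsupported(st, use = "bootstrap")
  by_pp <- collapse_unsupported(st, use = "posterior")
  expect_equal(by_bs$phy$Nnode, 3)   # both nodes >= 65
  expect_equal(by_pp$phy$Nnode, 2)   # PP 0.50 < 0.95 collapses
})

test_that("liberal classification covers the success/ambiguous/misidentified cases", {
  info <- data.frame(individual_id = c("q", "x1", "x2", "y1", "y2"),
                     genus = "G",
                     species = c("x", "x", "x", "y", "y"))
  # cherry with a conspecific
  st <- read_tree_text("(((q:1,x1:1)99:1,x2:2)99:1,(y1:1,y2:1)99:2);",
                       "bootstrap")
  expect_equal(liberal_classify(st, "q", info, "species")$category, "success")
  # polytomy with conspecific and allospecific
  st2 <- read_tree_text("((q:1,x1:1,y1:1)99:1,(x2:1,y2:1)99:1);", "bootstrap")
  expect_equal(liberal_classify(st2, "q", info, "species")$category,
               "ambiguous")
  # sister to a clade of allospecifics only
  st3 <- read_tree_text("((q:1,(y1:1,y2:1)99:1)99:1,(x1:1,x2:1)99:1);",
                        "bootstrap")
  expect_equal(liberal_classify(st3, "q", info, "species")$category,
               "misidentified")
  # no conspecific individual anywhere
  info2 <- info; info2$species <- c("q", "x", "x", "y", "y")
  expect_equal(liberal_classify(st, "q", info2, "species")$category,
               "ambiguous")
  expect_error(liberal_classify(st, "zz", info, "species"), "not a tip")
})

test_that("outgroup tips are excluded from taxon multisets", {
  info <- data.frame(individual_id = c("q", "x1", "og"),
                     genus = c("G", "G", "Out"),
                     species = c("x", "x", "o"))
  st <- read_tree_text("((q:1,x1:1,og:1)99:1,x1b:2);", "bootstrap")
  # without exclusion the outgroup pollutes the polytomy
  info2 <- rbind(info, data.frame(individual_id = "x1b", genus = "G",
                                  species = "x"))
  expect_equal(liberal_classify(st, "q", info2, "species")$category,
               "ambiguous")
  expect_equal(liberal_classify(st, "q", info2, "species",
                                exclude = "og")$category, "success")
})

test_that("monophyly reports match a naive MRCA oracle", {
  info <- data.frame(individual_id = c("a1", "a2", "b1", "b2"),
                     genus = "G", species = c("a", "a", "b", "b"))
  st <- read_tree_text("((a1:1,a2:1)99:1,(b1:1,b2:1)99:1);", "bootstrap")
  rep1 <- monophyly_report(st, info, "species")
  expect_true(all(rep1$status == "monophyletic"))
  st2 <- read_tree_text("((a1:1,b1:1)99:1,(a2:1,b2:1)99:1);", "bootstrap")
  rep2 <- monophyly_report(st2, info, "species")
  expect_true(all(rep2$status == "non-monophyletic"))
  # random labelled trees vs oracle
  set.seed(99)
  for (rep in 1:20) {
    phy <- ape::rtree(8)
    phy$tip.label <- sprintf("i%d", 1:8)
    st3 <- support_tree(phy, "bootstrap", bootstrap = rep(100, phy$Nnode))
    infr <- data.frame(individual_id = phy$tip.label, genus = "G",
                       species = sample(c("a", "b", "c"), 8, replace = TRUE))
    got <- monophyly_report(st3, infr, "species")
    for (k in seq_len(nrow(got))) {
      members <- infr$individual_id[paste("G", infr$species) == got$taxon[k]]
      if (length(members) == 1) {
        expect_equal(got$status[k], "singleton")
      } else {
        expect_equal(got$status[k] == "monophyletic",
                     oracle_monophyly(phy, members))
      }
    }
  }
})

test_that("classification is invariant to child rotation", {
  info <- data.frame(individual_id = c("q", "x1", "y1", "y2"),
                     genus = "G", species = c("x", "x", "y", "y"))
  a <- read_tree_text("((q:1,x1:1)99:1,(y1:1,y2:1)99:1);", "bootstrap")
  b <- read_tree_text("((y2:1,y1:1)99:1,(x1:1,q:1)99:1);", "bootstrap")
  expect_equal(liberal_classify(a, "q", info, "species")$category,
               liberal_classify(b, "q", info, "species")$category)
})

test_that("collapsing supports never turns success into misidentification", {
  set.seed(41)
  for (rep in 1:40) {
    pt <- simulate_ptp_tree(4, 3, rate_ratio = 15, seed = 500 + rep)
    st <- pt$tree
    st$bootstrap <- stats::runif(st$phy$Nnode, 0, 100)
    full <- liberal_classify_all(st, pt$info, "species")
    coll <- liberal_classify_all(collapse_unsupported(st, 65), pt$info,
                                 "species")
    for (q in full$query) {
      before <- full$category[full$query == q]
      after <- coll$category[coll$query == q]
      expect_false(before == "success" && after == "misidentified")
    }
  }
})
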
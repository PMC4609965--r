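test_that("region maps enforce tiling and hot-spot containment", {
  aseq <- synuclein_sequence("alpha")
  rm_a <- region_map(aseq)
  expect_equal(rm_a$regions$N, c(1L, 60L))
  expect_equal(rm_a$regions$NAC, c(61L, 95L))
  expect_equal(rm_a$regions$C, c(96L, 140L))
  bseq <- synuclein_sequence("beta")
  expect_equal(region_map(bseq)$regions$C, c(85L, 134L))
  # overlapping regions rejected
  expect_error(region_map(aseq, regions = list(N = c(1, 60), NAC = c(55, 95),
                                               C = c(96, 140))),
               class = "prekd_regions")
  # hot spot outside the N-terminal region rejected
  expect_error(region_map(aseq, hotspot = c(58, 70)), class = "prekd_regions")
  expect_equal(region_of(rm_a, c(11, 70, 132)), c("N", "NAC", "C"))
})

test_that("colour binning clamps at zero and saturates above 12", {
  expect_equal(bin_gamma2(c(-5, 0, 0.1, 2, 2.1, 8, 12, 12.0001, 50)),
               c(1L, 1L, 2L, 2L, 3L, 5L, 7L, 8L, 8L))
})

test_that("contact maps order strips by site and render idempotently", {
  rmap <- region_map(synuclein_sequence("alpha"),
                     mtsl_sites = c(11L, 44L, 90L, 132L))
  mk <- function(site) make_pp(1:140, rep(0, 140),
                               sample = list(visible_species = "alpha",
                                             label_site = site))
  profiles <- lapply(c(90L, 11L, 132L, 44L), mk)
  cmap <- build_contact_map(profiles, rmap)
  expect_equal(cmap$sites, c(11L, 44L, 90L, 132L))
  expect_equal(dim(cmap$binned), c(4L, 140L))
  cmap2 <- build_contact_map(profiles, rmap)
  expect_identical(cmap$binned, cmap2$binned)
  expect_identical(cmap$table, cmap2$table)
  # no significant residues anywhere: no top-bin cells
  expect_false(any(cmap$binned == 8L, na.rm = TRUE))
  # single strip is valid too
  expect_equal(length(build_contact_map(profiles[2], rmap)$strips), 1L)
  # inconsistent visible species rejected
  bad <- make_pp(1:140, rep(0, 140),
                 sample = list(visible_species = "beta", label_site = 44L))
  expect_error(build_contact_map(list(profiles[[1]], bad), rmap),
               class = "prekd_metadata")
})

test_that("region summaries count contiguous blocks and call topology", {
  rmap <- region_map(synuclein_sequence("alpha"), mtsl_sites = c(11L, 44L))
  # empty map: all counts zero, no topology
  flat <- make_pp(1:140, rep(0, 140),
                  sample = list(visible_species = "alpha", label_site = 44L))
  rs0 <- region_summary(build_contact_map(list(flat), rmap))
  expect_equal(sum(rs0$table$n_significant), 0)
  expect_length(rs0$topology, 0)
  # N-probe seeing an N block and a C block: head-to-head + head-to-tail
  g <- rep(0, 140); g[38:42] <- 20; g[126:131] <- 15
  both <- make_pp(1:140, g, sample = list(visible_species = "alpha",
                                          label_site = 44L))
  rs <- region_summary(build_contact_map(list(both), rmap))
  expect_setequal(rs$topology, c("head-to-head", "head-to-tail"))
  tabN <- rs$table[rs$table$region == "N", ]
  expect_equal(tabN$n_significant, 5)
  expect_equal(tabN$max_gamma2, 20)
  # two isolated single-residue passes do not count as an interaction
  g2 <- rep(0, 140); g2[c(38, 41)] <- 20
  iso <- make_pp(1:140, g2, sample = list(visible_species = "alpha",
                                          label_site = 44L))
  rs2 <- region_summary(build_contact_map(list(iso), rmap))
  expect_length(rs2$topology, 0)
})

test_that("contact map plot builds without error", {
  rmap <- region_map(synuclein_sequence("alpha"), mtsl_sites = 44L)
  g <- rep(0, 140); g[38:42] <- 20
  cmap <- build_contact_map(
    list(make_pp(1:140, g, sample = list(visible_species = "alpha",
                                         label_site = 44L))), rmap)
  gg <- plot(cmap)
  expect_s3_class(gg, "ggplot")
  built <- ggplot2::ggplot_build(gg)
  expect_gt(nrow(built$data[[1]]), 100)
})

test_that("global alignment maps residues and exposes gaps", {
  # identical sequences: identity map
  al <- align_sequences("MDVFMK", "MDVFMK")
  expect_equal(al$pos_a, 1:6)
  expect_equal(al$pos_b, 1:6)
  # tiny deletion: D unmapped, flanks map in register
  al <- align_sequences("ACDE", "ACE")
  expect_equal(al$pos_a, c(1L, 2L, 4L))
  expect_equal(al$pos_b, c(1L, 2L, 3L))
  expect_false(3L %in% al$pos_a)
})

test_that("synuclein alignment shows the 11-residue NAC deletion", {
  aseq <- synuclein_sequence("alpha")
  bseq <- synuclein_sequence("beta")
  expect_equal(nchar(aseq), 140L)
  expect_equal(nchar(bseq), 134L)
  al <- align_sequences(aseq, bseq)
  gaps_b <- gap_runs(attr(al, "aligned_b"))
  # alpha-sequence coordinate of each beta-side gap run
  apos <- cumsum(strsplit(attr(al, "aligned_a"), "")[[1]] != "-")
  nac <- region_map(aseq)$regions$NAC
  in_nac <- gaps_b[apos[gaps_b$start] >= nac[1] & apos[gaps_b$start] <= nac[2], ]
  expect_equal(nrow(in_nac), 1L)
  expect_equal(in_nac$length, 11L)
})
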
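test_that("map_sites converts peptide offsets to protein coordinates", {
  db <- c(PA = "AAARDEFGK", PB = "AAAKDEFGK")
  ev <- toy_evidence("DEFGK", "PA", 1)
  s <- map_sites(ev, db)
  expect_equal(s$positions, "5")
  expect_true(s$preceded_by_arg_at_peptide_start)

  s <- map_sites(toy_evidence("DEFGK", "PB", 1), db)
  expect_false(s$preceded_by_arg_at_peptide_start)  # preceded by K

  # published coordinate check: peptide starting at 67, mod offset 10 -> 76
  set.seed(8)
  pep <- "DTSLYRPALEELR"
  prot <- paste0(paste(sample(c("A", "G", "L", "S"), 66, TRUE),
                       collapse = ""), pep, "KAAA")
  s <- map_sites(toy_evidence(pep, "PX", 10), c(PX = prot))
  expect_equal(s$positions, "76")
  expect_equal(s$residues, "E")
})

test_that("unmapped evidence warns and is reported, ambiguity flagged", {
  db <- c(PA = "MDEFGKLMDEFGK")
  ev <- bind_evidence(toy_evidence("DEFGK", "PA", 1),    # two matches
                      toy_evidence("WWWWW", "PA", 1),    # absent
                      toy_evidence("DEFGK", "PZ", 1))    # unknown protein
  expect_warning(s <- map_sites(ev, db), "2 evidence record")
  expect_equal(nrow(s), 1L)
  expect_true(s$ambiguous)
  expect_equal(s$positions, "2")  # first exact match
  expect_equal(nrow(attr(s, "unmapped")), 2L)
})

test_that("records merge across samples keeping best loc and PEP", {
  db <- c(PA = "MAAADEFGKAAA")
  ev <- bind_evidence(
    toy_evidence("DEFGK", "PA", 1, loc = 0.8, pep = 0.005,
                 genotype = "WT", column_id = "c1"),
    toy_evidence("DEFGK", "PA", 1, loc = 0.95, pep = 0.02,
                 genotype = "WT", column_id = "c2"),
    toy_evidence("DEFGK", "PA", 1, loc = 0.6, pep = 0.001,
                 genotype = "KO", column_id = "c1"))
  s <- map_sites(ev, db)
  expect_equal(nrow(s), 1L)
  expect_equal(s$localization_probability, 0.95)
  expect_equal(s$pep, 0.001)
  expect_equal(s$genotypes_observed, "WT;KO")
})

test_that("preceding-Arg filter removes only peptide-start-after-R sites", {
  db <- c(P1 = "AAARDEFGK",   # R before peptide start
          P2 = "AAAKDEFGK",   # K before peptide start
          P3 = "DEFGKAAAA",   # peptide at protein N terminus
          P4 = "AARTDEFGK")   # internal mod, R before peptide
  ev <- bind_evidence(toy_evidence("DEFGK", "P1", 1),
                      toy_evidence("DEFGK", "P2", 1),
                      toy_evidence("DEFGK", "P3", 1),
                      toy_evidence("TDEFGK", "P4", 2))
  s <- apply_preceding_arg_filter(map_sites(ev, db))
  conf <- setNames(s$confidence, s$protein_id)
  expect_equal(unname(conf["P1"]), "removed")
  expect_true(is.na(conf["P2"]))
  expect_true(is.na(conf["P3"]))
  expect_true(is.na(conf["P4"]))
  expect_equal(nrow(attr(s, "removed")), 1L)
  # override list exempts a curated site
  s2 <- apply_preceding_arg_filter(map_sites(ev, db), keep = "P1")
  expect_true(all(is.na(s2$confidence)))
})

test_that("confidence classification applies exclusivity, loc and PEP", {
  ev <- bind_evidence(
    toy_evidence("DTSLYRPALEELR", "Psmd2", 10, loc = 0.95191,
                 pep = 0.00496884),
    toy_evidence("ESEEALQK", "Rrbp1", 4, loc = 0.930368, pep = 0.0146506),
    toy_evidence("MDEFGHK", "Kx", 2, loc = 0.99, pep = 0.001,
                 genotype = "KO"))
  s <- classify_confidence(map_sites(ev, db = NULL))
  conf <- setNames(s$confidence, s$protein_id)
  expect_equal(unname(conf["Psmd2"]), "high")
  expect_equal(unname(conf["Rrbp1"]), "medium")   # PEP above 0.01
  expect_equal(unname(conf["Kx"]), "nonspecific") # seen in KO

  # boundary: loc must exceed 0.75 strictly, PEP 0.01 passes
  b <- classify_confidence(map_sites(bind_evidence(
    toy_evidence("MDEK", "B1", 2, loc = 0.75, pep = 0.001),
    toy_evidence("MDEK", "B2", 3, loc = 0.76, pep = 0.01)), db = NULL))
  expect_equal(setNames(b$confidence, b$protein_id)[c("B1", "B2")],
               c(B1 = "medium", B2 = "high"))
})

test_that("classification is threshold-monotone into the high tier", {
  set.seed(12)
  base <- map_sites(bind_evidence(
    toy_evidence("MDEK", "P1", 2, loc = 0.8, pep = 0.004),
    toy_evidence("MDDK", "P2", 3, loc = 0.97, pep = 0.02),
    toy_evidence("MEEK", "P3", 2, loc = 0.7, pep = 0.0005)), db = NULL)
  locs <- c(0.5, 0.75, 0.9, 0.99)
  peps <- c(0.05, 0.01, 0.001)
  high_sets <- list()
  for (lt in locs) for (pt in peps) {
    s <- classify_confidence(base, loc_threshold = lt, pep_threshold = pt)
    high_sets[[paste(lt, pt)]] <- s$protein_id[s$confidence == "high"]
  }
  for (i in seq_along(locs)[-1]) for (pt in peps) {
    expect_true(all(high_sets[[paste(locs[i], pt)]] %in%
                    high_sets[[paste(locs[i - 1], pt)]]))
  }
  for (lt in locs) for (j in seq_along(peps)[-1]) {
    expect_true(all(high_sets[[paste(lt, peps[j])]] %in%
                    high_sets[[paste(lt, peps[j - 1])]]))
  }
})

test_that("tiers partition the records and summaries count first genes", {
  ev <- bind_evidence(
    toy_evidence("MDEK", "A", 2, gene = "Ga; Gx"),
    toy_evidence("MDDK", "B", 3, gene = "Ga; Gy"),
    toy_evidence("MEEK", "C", 2, gene = "Gb", genotype = "KO"))
  s <- classify_confidence(apply_preceding_arg_filter(
    map_sites(ev, db = NULL)))
  expect_false(anyNA(s$confidence))
  sm <- summarize_sites(s)
  expect_equal(sm$n_sites[sm$confidence == "high"], 2L)
  expect_equal(sm$n_proteins[sm$confidence == "high"], 1L)  # both Ga
  expect_equal(sm$n_sites[sm$confidence == "nonspecific"], 1L)
  expect_equal(summarize_sites(s[0, ])$n_sites, rep(0L, 4))
})

test_that("residue granularity explodes multi-site rows", {
  db <- c(PA = "MSLDRLFGCERVTN")
  ev <- toy_evidence("SLDRLFGCERVTN", "PA", c(3, 9))
  row <- map_sites(ev, db, site_granularity = "row")
  expect_equal(nrow(row), 1L)
  expect_equal(row$positions, "4;10")
  res <- map_sites(ev, db, site_granularity = "residue")
  expect_equal(nrow(res), 2L)
  expect_equal(sort(res$positions), c("10", "4"))
})

test_that("simulated truth separates tiers as designed", {
  w <- simulate_experiment(sim_config(n_proteins = 400, seed = 33))
  s <- classify_confidence(apply_preceding_arg_filter(
    map_sites(w$evidence, w$db)))
  truth <- w$truth$sites
  key <- function(p, pos) paste(p, pos)
  conf_by_key <- setNames(s$confidence, key(s$protein_id, s$positions))
  tconf <- conf_by_key[key(truth$protein_id, truth$position)]
  expect_false(anyNA(tconf))
  # every KO contaminant is nonspecific
  expect_true(all(tconf[truth$is_ko_contaminant] == "nonspecific"))
  # artifact sites are removed
  expect_true(all(tconf[truth$is_preceded_by_arg_artifact] == "removed"))
  # >= 95% of clean true sites classify high
  clean <- truth$is_true_site & !truth$is_preceded_by_arg_artifact
  expect_gte(mean(tconf[clean] == "high"), 0.95)
})
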
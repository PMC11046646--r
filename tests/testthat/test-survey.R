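test_that("signal-peptide detection follows the cleavage motif rules", {
  # constructed instance of the motif: G at 0-based index 5, E at index 10
  seq1 <- "MKVLQGFTLIELLIVVAIIGILAAVAIPQYQNYVARSE"
  hit <- detect_spiii(seq1)
  expect_equal(hit$index, 5)
  expect_true(hit$strict)
  expect_equal(substr(seq1, hit$index + 2, hit$index + 2), "F")
  # no Gly anywhere -> absent
  expect_null(detect_spiii("MKVLQATLIELLIVVAIIAILAAVAIPQY"))
})

test_that("first-match semantics and the fallback hydrophobic set", {
  two <- paste0("MKVLGFAAAE", paste(rep("A", 19), collapse = ""), "GFTTTEAAAA")
  expect_equal(detect_spiii(two)$index, 4)
  # fallback: Ile at +1 only found when no strict match exists
  fb <- "MKVLQGITLIELLIVVAIIGILAAVAIPQYQNYVARSE"
  hit <- detect_spiii(fb)
  expect_equal(hit$index, 5)
  expect_false(hit$strict)
  # strict match downstream beats an earlier fallback match
  mixed <- paste0("MKGIXXXE", paste(rep("K", 10), collapse = ""), "GFTTTEAAAAAAA")
  hit2 <- detect_spiii(mixed)
  expect_equal(hit2$index, 18)
  expect_true(hit2$strict)
  # invalid characters error
  expect_error(detect_spiii("MKVLQGFTLIE*LLIVVAIIGILAAVAIPQ"), "non-amino-acid")
  # mature sequence starting with F is never cleaved inside residue 1
  mature <- "FTLIELLIVVAIIGILAAVAIPQYQNYVARSEG"
  h <- detect_spiii(mature)
  expect_true(is.null(h) || h$index > 0)
})

test_that("length classification applies the >=166 threshold to mature length", {
  mk <- function(mature_len) {
    paste0("MKVLQG", paste0("F", "AAA", "E",
                            paste(rep("L", mature_len - 5), collapse = "")))
  }
  rec <- prepilin_records(c("a", "b", "c"),
                          c(mk(165), mk(166), mk(208)))
  rec <- classify_length(rec)
  expect_equal(rec$mature_length, c(165, 166, 208))
  expect_equal(rec$size_class, c("standard", "large", "large"))
  # a record without a motif stays unclassified but is counted
  rec2 <- classify_length(prepilin_records("x", paste(rep("K", 50), collapse = "")))
  expect_equal(rec2$size_class, "unclassified")
  s <- summarize_taxa(rbind(rec, rec2))
  expect_equal(s$global$n + s$n_dropped, 4)
})

test_that("greedy clustering matches a brute-force identity oracle", {
  ps <- simulate_prepilin_set(
    31, taxa = data.frame(phylum = "P", class = "C", n = 40, frac_large = NA),
    length_mean = 60, length_sd = 8, length_range = c(42, 90),
    dup_rate = 0.25)
  rec <- prepilin_records(ps$records$id, ps$records$sequence)
  expect_equal(nrow(rec), 50)
  cl <- cluster_identity(rec, 0.90)
  # oracle: brute-force all-pairs identity, then the same greedy rule
  ord <- order(-nchar(rec$sequence), rec$id)
  reps <- integer(0)
  for (i in ord) {
    hit <- FALSE
    for (r in reps) {
      if (nw_identity(rec$sequence[r], rec$sequence[i]) > 0.90) { hit <- TRUE; break }
    }
    if (!hit) reps <- c(reps, i)
  }
  expect_setequal(cl$retained$id, rec$id[reps])
  # every planted duplicate was absorbed
  expect_false(any(grepl("_dup", cl$retained$id)))
  # invariant under input shuffling
  set.seed(9)
  shuf <- rec[sample.int(nrow(rec)), ]
  cl2 <- cluster_identity(shuf, 0.90)
  expect_setequal(cl2$retained$id, cl$retained$id)
  # idempotence
  cl3 <- cluster_identity(cl$retained, 0.90)
  expect_equal(sort(cl3$retained$id), sort(cl$retained$id))
  # boundary semantics on tiny cases
  two <- prepilin_records(c("s1", "s2"),
                          rep("MKVLQGFTLIELLIVVAIIGILAAVAIPQYQNYVARSE", 2))
  expect_equal(nrow(cluster_identity(two, 0.90)$retained), 1)
  ab <- prepilin_records(c("a1", "a2"), c(
    "MKVLQGFTLIELLIVVAIIGILAAVAIPQYQNYVARSE",
    "MKVLQGFTLIELLIVCCIIGWLAAVCIPQYQNYVCRSE"))
  expect_equal(nrow(cluster_identity(ab, 0.90)$retained), 2)
})

test_that("taxon summaries count exactly what was planted", {
  ps <- simulate_prepilin_set(7, taxa = data.frame(
    phylum = c("P1", "P1", "P2"), class = c("C1", "C2", "C3"),
    n = c(60, 30, 30), frac_large = c(0, 1, NA)))
  rec <- classify_length(prepilin_records(ps$records$id, ps$records$sequence,
                                          ps$records$phylum, ps$records$class))
  s <- summarize_taxa(rec)
  expect_equal(s$global$n, 120)
  pc <- s$per_class
  expect_equal(pc$pct_large[pc$taxon == "C1"], 0)
  expect_equal(pc$pct_large[pc$taxon == "C2"], 100)
  expect_equal(pc$n[pc$taxon == "C2"], 30)
  expect_true(all(pc$length_min <= pc$length_mean & pc$length_mean <= pc$length_max))
  # single record: mean = its length, SD 0
  one <- classify_length(prepilin_records("z", paste0(
    "MKVLQGF", "AAAE", paste(rep("L", 139), collapse = ""))))
  s1 <- summarize_taxa(one)
  expect_equal(s1$global$length_mean, one$mature_length)
  expect_equal(s1$global$length_sd, 0)
  expect_equal(s1$global$pct_large, 0)
  expect_error(summarize_taxa(one[0, ]))
})

test_that("consensus profile flags planted conserved positions", {
  ps <- simulate_prepilin_set(13, taxa = data.frame(
    phylum = "P", class = "C", n = 120, frac_large = NA), p22_freq = 0.8)
  rec <- classify_length(prepilin_records(ps$records$id, ps$records$sequence))
  cp <- consensus_profile(rec)
  expect_equal(nrow(cp), 55)
  expect_equal(cp$residue[cp$position == 1], "F")
  expect_equal(cp$frequency[cp$position == 1], 1)
  expect_equal(cp$residue[cp$position == 5], "E")
  expect_true(cp$conserved[cp$position == 22])
  expect_equal(cp$residue[cp$position == 22], "P")
  expect_lt(cp$frequency[cp$position == 22], 1)
  # all-identical sequences: every covered position conserved at 1.0
  same <- classify_length(prepilin_records(
    c("u", "v"), rep("MKVLQGFTLIELLIVVAIIGILAAVAIPQYQNYVARSE", 2)))
  cps <- consensus_profile(same)
  covered <- cps[cps$coverage > 0, ]
  expect_true(all(covered$frequency == 1))
  expect_true(all(covered$conserved))
  expect_true(all(cps$coverage[cps$position > 32] == 0))
})
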
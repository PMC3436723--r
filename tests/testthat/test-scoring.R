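sig_tbl <- function(...) {
  rows <- list(...)
  tibble::tibble(
    uuid = vapply(rows, `[[`, character(1), 1L),
    signature = vapply(rows, `[[`, character(1), 2L)
  )
}

test_that("the index counts document frequency over distinct molecules", {
  idx <- build_index(sig_tbl(c("U1", "A"), c("U1", "A"), c("U1", "B"),
                             c("U2", "A")))
  expect_equal(idx$counts[["A"]], 2L)  # U1's duplicate A counts once
  expect_equal(idx$counts[["B"]], 1L)
  expect_equal(idx$total_molecules, 2L)

  single <- build_index(sig_tbl(c("U", "s")))
  expect_equal(unname(single$counts), 1L)
  expect_equal(single$total_molecules, 1L)

  expect_error(build_index(sig_tbl()), class = "npl_training_error")
})

test_that("index counts equal a brute-force per-molecule rescan", {
  mols <- small_fixture_set(50, seed = 17)
  sigs <- sign_batch(mols, 2)
  idx <- build_index(sigs)
  by_mol <- split(sigs$signature, sigs$uuid)
  for (s in names(idx$counts)) {
    brute <- sum(vapply(by_mol, function(x) s %in% x, logical(1)))
    expect_equal(unname(idx$counts[[s]]), brute)
  }
  expect_equal(idx$total_molecules, length(by_mol))
})

test_that("fragment scores reproduce the log frequency-ratio by hand", {
  np <- sig_tbl(c("n1", "A"), c("n2", "A"), c("n3", "B"), c("n4", "B"),
                c("n5", "B"), c("n6", "C"), c("n7", "C"), c("n8", "C"),
                c("n9", "C"), c("n10", "C"))
  sm <- sig_tbl(c("s1", "A"), c("s2", "B"), c("s3", "B"), c("s4", "B"),
                c("s5", "C"), c("s6", "C"), c("s7", "C"), c("s8", "C"),
                c("s9", "C"), c("s10", "C"))
  model <- scorer_model(np, sm, alpha = 0)
  # NP_A = 2, SM_A = 1, NP_t = SM_t = 10 -> ln 2
  expect_equal(fragment_score("A", model)$value, log(2), tolerance = 1e-12)
  # equal counts on both sides -> exactly 0
  expect_identical(fragment_score("B", model)$value, 0)

  same <- scorer_model(np, np, alpha = 0)
  expect_identical(fragment_score(c("A", "B", "C"), same)$value, c(0, 0, 0))

  smoothed <- scorer_model(np, sm, alpha = 1)
  expect_equal(fragment_score("unseen", smoothed)$value, 0, tolerance = 1e-15)
  expect_error(fragment_score("unseen", model), class = "npl_undefined_score")
})

test_that("molecule scores are the atom-normalised fragment sums", {
  np <- sig_tbl(c("n1", "A"), c("n2", "A"), c("n3", "B"))
  sm <- sig_tbl(c("s1", "A"), c("s2", "B"), c("s3", "B"))
  model <- scorer_model(np, sm, alpha = 0)
  # A scores ln((2/1)*(3/3)) = ln 2; B scores ln((1/2)*(3/3)) = -ln 2
  query <- sig_tbl(c("q", "A"), c("q", "A"), c("q", "B"))
  res <- score_molecules(query, model)
  expect_equal(res$raw_sum, log(2), tolerance = 1e-12)
  expect_equal(res$n_atoms, 3L)
  expect_equal(res$np_likeness, log(2) / 3, tolerance = 1e-12)

  # {ln2, ln2, 0} averages to 2 ln2 / 3 ~ 0.462098
  query2 <- sig_tbl(c("q2", "A"), c("q2", "A"), c("q2", "unseen"))
  model1 <- scorer_model(np, sm, alpha = 1)
  v <- fragment_score(c("A", "unseen"), model1)$value
  res2 <- score_molecules(query2, model1)
  expect_equal(res2$np_likeness, (2 * v[1] + v[2]) / 3, tolerance = 1e-12)

  # a molecule and its disjoint double score identically
  dbl <- rbind(query, query)
  expect_equal(score_molecules(dbl, model)$np_likeness,
               res$np_likeness, tolerance = 1e-15)
})

test_that("results come back in first-appearance order of uuids", {
  np <- sig_tbl(c("n", "A")); sm <- sig_tbl(c("s", "A"))
  model <- scorer_model(np, sm)
  q <- sig_tbl(c("z", "A"), c("a", "A"), c("z", "A"), c("m", "A"))
  expect_equal(score_molecules(q, model)$uuid, c("z", "a", "m"))
})

test_that("swapping the corpora negates every score exactly", {
  mols <- small_fixture_set(40, seed = 23)
  half <- seq_len(20)
  np <- sign_batch(mols[half, ]); sm <- sign_batch(mols[-half, ])
  q <- sign_batch(small_fixture_set(10, seed = 24))
  fwd <- score_molecules(q, scorer_model(np, sm, alpha = 1))
  rev <- score_molecules(q, scorer_model(sm, np, alpha = 1))
  expect_identical(fwd$np_likeness, -rev$np_likeness)
  expect_identical(fwd$raw_sum, -rev$raw_sum)
})

test_that("duplicating both corpora leaves every score unchanged", {
  # exact scaling invariance belongs to the literal frequency ratio, so use
  # alpha = 0 with a query vocabulary covered by both corpora
  mols <- small_fixture_set(60, seed = 29)
  np <- sign_batch(mols[1:40, ])
  sm <- sign_batch(mols[21:60, ])
  q <- sign_batch(mols[21:40, ])
  dup <- function(s) rbind(s, dplyr::mutate(s, uuid = paste0(uuid, "-copy")))
  a <- score_molecules(q, scorer_model(np, sm, alpha = 0))
  b <- score_molecules(q, scorer_model(dup(np), dup(sm), alpha = 0))
  expect_equal(a$np_likeness, b$np_likeness, tolerance = 1e-12)
  expect_true(any(a$np_likeness != 0))
})

test_that("a molecule score never exceeds its largest fragment score", {
  mols <- small_fixture_set(30, seed = 31)
  np <- sign_batch(mols[1:15, ]); sm <- sign_batch(mols[16:30, ])
  model <- scorer_model(np, sm, alpha = 1)
  q <- sign_batch(small_fixture_set(10, seed = 32))
  res <- score_molecules(q, model)
  for (u in res$uuid) {
    fs <- fragment_score(q$signature[q$uuid == u], model)$value
    expect_lte(abs(res$np_likeness[res$uuid == u]), max(abs(fs)) + 1e-12)
  }
})

test_that("a saved model reloads to identical scores", {
  mols <- small_fixture_set(30, seed = 37)
  np <- sign_batch(mols[1:15, ]); sm <- sign_batch(mols[16:30, ])
  model <- scorer_model(np, sm, height = 2, alpha = 1)
  path <- withr::local_tempfile(fileext = ".npl")
  save_model(model, path)
  back <- load_model(path)
  expect_identical(back$np_index$counts, model$np_index$counts)
  expect_identical(back$sm_index$counts, model$sm_index$counts)
  expect_identical(back$height, model$height)
  expect_identical(back$alpha, model$alpha)
  q <- sign_batch(small_fixture_set(10, seed = 38))
  expect_identical(score_molecules(q, back)$np_likeness,
                   score_molecules(q, model)$np_likeness)

  bad <- withr::local_tempfile(fileext = ".npl")
  writeLines("some-other-format\t9", bad)
  expect_error(load_model(bad), class = "npl_model_version_error")
})

test_that("top_fragments ranks by score with lexicographic tie-breaks", {
  np <- sig_tbl(c("n1", "A"), c("n1", "B"), c("n2", "A"))
  sm <- sig_tbl(c("s1", "B"), c("s1", "C"), c("s2", "C"))
  model <- scorer_model(np, sm, alpha = 1)
  all_fs <- top_fragments(model, k = 100)
  expect_equal(nrow(all_fs), 3L)  # k beyond vocabulary: whole vocabulary
  expect_true(!is.unsorted(rev(all_fs$value)))
  top <- top_fragments(model, k = 1, direction = "np_like")
  expect_equal(top$signature, "A")
  bottom <- top_fragments(model, k = 1, direction = "synthetic_like")
  expect_equal(bottom$signature, "C")

  mols <- small_fixture_set(10, seed = 41)
  model2 <- scorer_model(sign_batch(mols[1:5, ]), sign_batch(mols[6:10, ]))
  decoded <- top_fragments(model2, k = 5, decode = TRUE)
  for (i in seq_len(nrow(decoded))) {
    d <- decoded$mol[[i]]
    expect_identical(atom_signature(d, attr(d, "root"), 2),
                     decoded$signature[i])
  }
})

test_that("density plots overlay one curve per named set and write PDF", {
  res1 <- tibble::tibble(uuid = letters[1:10], np_likeness = rnorm(10))
  res2 <- tibble::tibble(uuid = letters[11:20], np_likeness = rnorm(10, 1))
  p <- plot_score_density(natural = res1, synthetic = res2)
  expect_s3_class(p, "ggplot")
  expect_setequal(unique(p$data$set), c("natural", "synthetic"))

  path <- withr::local_tempfile(fileext = ".pdf")
  plot_score_density(natural = res1, synthetic = res2, path = path)
  expect_true(file.exists(path) && file.size(path) > 0)

  flat <- tibble::tibble(uuid = letters[1:5], np_likeness = rep(1.5, 5))
  pf <- plot_score_density(constant = flat)
  peak <- pf$data$np_likeness[which.max(pf$data$density)]
  expect_equal(peak, 1.5, tolerance = 0.01)

  expect_error(plot_score_density(res1), regexp = "named")
})
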
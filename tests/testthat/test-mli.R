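test_that("MLI is the fraction of products carrying each key", {
  lex <- default_lexicon()
  set.seed(1)
  one <- compute_mli(flavour_products(6, 10), lex)
  expect_equal(one$mli[["flavour"]], 0.6)
  expect_equal(one$mli[["category:flavour"]], 0.6)
  expect_equal(one$mli[["UPF"]], 0.6)
  expect_equal(one$n_products, 10L)

  clean <- compute_mli(flavour_products(0, 1), lex)
  expect_true(all(clean$mli == 0))
  expect_equal(clean$mli[["UPF"]], 0)

  expect_error(compute_mli(flavour_products(0, 0), lex), "no products")
})

test_that("MLI equals a brute-force recount, including truncation", {
  lex <- default_lexicon()
  set.seed(42)
  terms <- c(flavour = "flavouring", lactose = "lactose",
             emulsifier = "emulsifier", sucralose = "E955")
  for (r in 1:20) {
    with_marker <- vapply(names(terms), function(m) sample(0:10, 1),
                          integer(1))
    texts <- vapply(1:10, function(j) {
      ing <- c("water", "salt")
      for (m in names(terms)) if (j <= with_marker[[m]])
        ing <- c(ing, terms[[m]])
      paste(ing, collapse = ", ")
    }, character(1))
    prods <- data.frame(item_id = "it", ingredients_text = texts,
                        portion_g = 100, energy_kj_100g = 1000)
    for (k in c(10L, 8L, 6L, 4L)) {
      got <- compute_mli(prods, lex, max_products = k)$mli
      for (m in names(terms)) {
        # brute-force recount on the (truncated) list
        expect_equal(got[[m]], sum(seq_len(k) <= with_marker[[m]]) / k,
                     label = sprintf("%s at k=%d rep %d", m, k, r))
      }
      expect_equal(got[["UPF"]], sum(seq_len(k) <= max(with_marker)) / k)
    }
  }
})

test_that("portion resolution: grams, specific gravity, fallback", {
  expect_equal(resolve_portion(100, "g"), 100)
  expect_equal(resolve_portion(100, "ml", "tea",
                               gravity = c(tea = 1.03)), 103)
  expect_equal(resolve_portion(1, "Mug/Cup", "tea",
                               fallback_g = c(tea = 250)), 250)
  expect_error(resolve_portion(1, "Mug/Cup", "tea"), "fallback")
  expect_error(resolve_portion(-5, "g", "x"), "onpositive")
})

test_that("marker grams scale the portion by the MLI", {
  expect_equal(item_marker_grams(50, 0.6), 30)
  expect_equal(item_marker_grams(50, 0), 0)
  expect_equal(item_marker_grams(50, 1), 50)
  expect_error(item_marker_grams(-1, 0.5))
  expect_error(item_marker_grams(10, 1.2))
})

test_that("recall exposure sums portioned grams and energy", {
  lex <- default_lexicon()
  mli <- build_mli_table(flavour_products(6, 10), lex)
  rec <- data.frame(item_id = "item001", n_portions = 1)
  got <- recall_exposure(rec, mli)
  expect_equal(got$total_food_g, 50)
  expect_equal(got$marker_g[["flavour"]], 30)   # 50 g * 0.6 MLI
  expect_equal(got$total_energy_kj, 50 * 2000 / 100)

  empty <- recall_exposure(rec[0, ], mli)
  expect_equal(empty$total_food_g, 0)
  expect_true(all(empty$marker_g == 0))

  expect_error(recall_exposure(data.frame(item_id = "nope", n_portions = 1),
                               mli), "nope")
})

test_that("recall exposure equals an item-by-item loop oracle", {
  lex <- default_lexicon()
  set.seed(5)
  prods <- do.call(rbind, lapply(1:6, function(i)
    flavour_products(sample(0:10, 1), 10, sprintf("item%03d", i),
                     portion_g = runif(1, 20, 300),
                     energy = runif(1, 200, 2400))))
  mli <- build_mli_table(prods, lex)
  for (r in 1:10) {
    ids <- sample(mli$items$item_id, sample(2:6, 1))
    rec <- data.frame(item_id = ids,
                      n_portions = sample(1:3, length(ids), TRUE))
    got <- recall_exposure(rec, mli)
    tot <- 0; flav <- 0
    for (i in seq_len(nrow(rec))) {
      k <- match(rec$item_id[i], mli$items$item_id)
      tot <- tot + rec$n_portions[i] * mli$items$mean_portion_g[k]
      flav <- flav + rec$n_portions[i] * mli$items$mean_portion_g[k] *
        mli$mli[k, "flavour"]
    }
    expect_equal(got$total_food_g, tot)
    expect_equal(got$marker_g[["flavour"]], flav)
  }
})

test_that("%TFI is the ratio of mean marker grams to mean total grams", {
  lex <- default_lexicon()
  # item A: always flavoured, portion 1000 g; item B: never, portion 1000 g
  pa <- flavour_products(10, 10, "A", portion_g = 1000)
  pb <- flavour_products(0, 10, "B", portion_g = 1000)
  mli <- build_mli_table(rbind(pa, pb), lex)
  rec <- data.frame(recall_index = 1L, item_id = c("A", "B"),
                    n_portions = 1)
  prof <- build_profile(rec, mli)
  expect_equal(prof$tfi[["flavour"]], 50)       # 1000 g / 2000 g
  expect_equal(prof$tfi[["UPF"]], 50)
  expect_equal(prof$total_food_g, 2000)

  # hand-checked 3-recall fixture: ratio of means, not mean of ratios
  rec3 <- data.frame(recall_index = c(1L, 2L, 3L),
                     item_id = c("A", "B", "A"),
                     n_portions = c(1, 2, 1))
  prof3 <- build_profile(rec3, mli)
  # recall grams: flavoured (1000, 0, 1000), total (1000, 2000, 1000)
  expect_equal(prof3$tfi[["flavour"]],
               100 * mean(c(1000, 0, 1000)) / mean(c(1000, 2000, 1000)))
  # first-recall mode uses recall 1 only
  prof1 <- build_profile(rec3, mli, mode = "first_recall")
  expect_equal(prof1$tfi[["flavour"]], 100)

  bad <- data.frame(recall_index = 1L, item_id = "B", n_portions = 1)
  mli0 <- build_mli_table(
    data.frame(item_id = "B", ingredients_text = "water",
               portion_g = 1e-300, energy_kj_100g = 0), lex)
  # zero-total guard (forced by a degenerate catalogue)
  expect_error(build_profile(data.frame(recall_index = 1L, item_id = "B",
                                        n_portions = 1e-300), mli0),
               "zero total intake")
})

test_that("%TFI is invariant to rescaling all portions", {
  lex <- default_lexicon()
  set.seed(8)
  prods <- do.call(rbind, lapply(1:5, function(i)
    flavour_products(sample(0:10, 1), 10, sprintf("it%d", i),
                     portion_g = runif(1, 50, 200))))
  prods2 <- prods; prods2$portion_g <- prods2$portion_g * 2
  mli1 <- build_mli_table(prods, lex)
  mli2 <- build_mli_table(prods2, lex)
  rec <- data.frame(recall_index = 1L, item_id = sprintf("it%d", 1:5),
                    n_portions = sample(1:3, 5, TRUE))
  p1 <- build_profile(rec, mli1)
  p2 <- build_profile(rec, mli2)
  expect_equal(p1$tfi, p2$tfi)
  expect_true(all(p1$tfi >= 0 & p1$tfi <= 100))
})

test_that("MLI and %TFI respect the UPF >= category >= marker ordering", {
  set.seed(21)
  cfg <- sim_config(seed = 31, n_items = 30, n_participants = 40)
  cat_ <- gen_catalogue(cfg)
  lex <- default_lexicon()
  mli <- build_mli_table(cat_$catalogue, lex, gravity = cat_$gravity,
                         fallback_g = cat_$fallback_g)
  for (cc in lex$categories) {
    expect_true(all(mli$mli[, "UPF"] >= mli$mli[, paste0("category:", cc)] - 1e-12))
    for (m in category_markers(lex, cc))
      expect_true(all(mli$mli[, paste0("category:", cc)] >= mli$mli[, m] - 1e-12))
  }
  coh <- gen_cohort(cfg, cat_)
  prof <- build_profiles(coh$recalls, mli)
  for (cc in lex$categories)
    expect_true(all(prof$tfi[, "UPF"] >= prof$tfi[, paste0("category:", cc)] - 1e-9))
})

test_that("cumulative intake sums the specific markers only", {
  x <- c("UPF" = 60, "category:flavour" = 3, "category:sweetener" = 2,
         "flavour" = 3, "acesulfame" = 2, "emulsifier" = 5)
  expect_equal(cumulative_intake(x), 10)
  expect_equal(cumulative_intake(x * 0), 0)
  set.seed(3)
  lex <- default_lexicon()
  keys <- exposure_keys(lex)
  for (r in 1:20) {
    v <- stats::setNames(runif(length(keys), 0, 5), keys)
    expect_equal(cumulative_intake(v), sum(v[specific_marker_keys(lex)]))
  }
})
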
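test_that("effective suitability handles scalar and guild-resolved parcels", {
  w <- default_guild_weights()
  scalar <- parcels("p1", "wetland", 1, suitability = 0.75)
  expect_equal(effective_suitability(scalar), 0.75)

  keys <- guild_stage_keys()$keys
  uniform <- parcels("p2", "embayment", 1, suitability = NA_real_,
                     suit_map = list(setNames(rep(0.5, 9), keys)))
  expect_equal(effective_suitability(uniform, w), 0.5)

  # warm-guild-only wetland: (19 + 22 + 19) / 100 = 0.60
  warm_only <- setNames(rep(0, 9), keys)
  warm_only[c("warm.spawning", "warm.nursery", "warm.juv_ad")] <- 1
  p <- parcels("p3", "wetland", 1, suitability = NA_real_,
               suit_map = list(warm_only))
  expect_equal(effective_suitability(p, w), 0.60)

  expect_error(effective_suitability(p), "weight table")
  incomplete <- parcels("p4", "wetland", 1, suitability = NA_real_,
                        suit_map = list(c(cold.spawning = 0.5)))
  expect_error(effective_suitability(incomplete, w), "missing keys")
  terr_map <- parcels("p5", "terrestrial", 1, suitability = NA_real_,
                      suit_map = list(setNames(rep(0.5, 9), keys)))
  expect_error(effective_suitability(terr_map, w), "no guild weight column")
})

test_that("WSA is area times suitability, summed per ecotype", {
  one <- parcels("w1", "wetland", 1, 0.75)
  expect_equal(compute_wsa(one)$wsa, 0.75)

  third <- parcels("w2", "wetland", 0.33, 0.75)
  expect_equal(compute_wsa(third)$wsa, 0.2475)

  expect_equal(nrow(compute_wsa(parcels())), 0)

  # retired parcels never re-enter valuation totals
  mixed <- parcels(c("a", "b"), "wetland", c(1, 2), 0.5,
                   status = c("tradable", "retired"))
  expect_equal(compute_wsa(mixed)$wsa, 0.5)
})

test_that("PWSA scales WSA by PPI and totals across ecotypes", {
  eco <- default_ecotypes()
  wsa <- tibble::tibble(ecotype = c("rivermouth", "wetland", "terrestrial"),
                        wsa = c(12.50, 27.50, 99))
  out <- compute_pwsa(wsa, eco)
  expect_equal(out$pwsa[out$ecotype == "rivermouth"], 18.75)
  expect_equal(out$pwsa[out$ecotype == "wetland"], 55.00)
  expect_equal(out$pwsa[out$ecotype == "terrestrial"], 0)
  expect_equal(attr(out, "total_pwsa"), 18.75 + 55)
  expect_error(compute_pwsa(tibble::tibble(ecotype = "lagoon", wsa = 1), eco),
               "unknown ecotype")
})

test_that("quality classification uses half-open midpoint bands", {
  expect_equal(as.character(classify_quality(c(0.75, 0.50, 0.25))),
               c("High", "Med", "Low"))
  expect_equal(as.character(classify_quality(c(0.625, 0.624999, 0.375,
                                               0.374999))),
               c("High", "Med", "Med", "Low"))
  expect_error(classify_quality(1.2), "outside")
  expect_error(classify_quality(-0.1), "outside")
})

test_that("quality distribution reproduces the published class totals", {
  base <- make_toronto_fixture(include_journal = FALSE)
  q <- quality_distribution(base$parcels, base$guild_weights)
  tot <- attr(q, "class_totals")
  expect_equal(unname(tot["High"]), 9881)
  expect_equal(unname(tot["Med"]), 3991)
  expect_equal(unname(tot["Low"]), 1588)
  # per-ecotype class hectares sum to the ecotype area
  per_eco <- tapply(q$area_ha, q$ecotype, sum)
  expect_equal(as.numeric(per_eco[c("rivermouth", "wetland", "embayment",
                                    "open_coast", "offshore")]),
               c(30, 160, 830, 14000, 440))

  single <- quality_distribution(parcels("p", "wetland", 10, 0.9))
  expect_equal(unname(attr(single, "class_totals")),
               c(10, 0, 0))
})

test_that("valuation is additive over disjoint inventories", {
  for (seed in 1:4) {
    a <- random_parcels(8, seed)
    b <- random_parcels(8, seed + 100)
    b$parcel_id <- paste0("q", b$parcel_id)
    va <- valuation(a)
    vb <- valuation(b)
    vab <- valuation(bind_parcels(a, b))
    expect_equal(vab$wsa, va$wsa + vb$wsa)
    expect_equal(vab$pwsa, va$pwsa + vb$pwsa)
    expect_equal(attr(vab, "total_pwsa"),
                 attr(va, "total_pwsa") + attr(vb, "total_pwsa"))
  }
})

test_that("total PWSA is monotone in area, suitability and PPI", {
  p <- random_parcels(12, 7)
  eco <- default_ecotypes()
  base <- attr(valuation(p, eco), "total_pwsa")
  for (i in c(1, 5, 9)) {
    up <- p
    up$area_ha[i] <- up$area_ha[i] * 2
    expect_gte(attr(valuation(up, eco), "total_pwsa"), base)
    up <- p
    up$suitability[i] <- min(1, up$suitability[i] + 0.2)
    expect_gte(attr(valuation(up, eco), "total_pwsa"), base)
  }
  eco_up <- eco
  eco_up$ppi[eco_up$name == "embayment"] <- 2.5
  expect_gte(attr(valuation(p, eco_up), "total_pwsa"), base)
})

test_that("rollup matches the brute-force per-parcel oracle", {
  w <- default_guild_weights()
  eco <- default_ecotypes()
  keys <- guild_stage_keys()$keys
  for (seed in 1:5) {
    p <- random_parcels(withr::with_seed(seed, sample(3:20, 1)), seed)
    # convert a couple of parcels to guild-resolved maps
    p2 <- withr::with_seed(seed + 1, {
      idx <- which(p$ecotype != "terrestrial")
      for (i in utils::head(idx, 2)) {
        p$suit_map[[i]] <- setNames(round(runif(9), 3), keys)
        p$suitability[i] <- NA_real_
      }
      p
    })
    v <- valuation(p2, eco, w)
    ora <- oracle_totals(p2, eco, w)
    expect_equal(attr(v, "total_wsa"), ora$wsa)
    expect_equal(attr(v, "total_pwsa"), ora$pwsa)
  }
})

test_that("wsa_e <= area_e and pwsa_e <= ppi_e * area_e always hold", {
  eco <- default_ecotypes()
  for (seed in 1:5) {
    v <- valuation(random_parcels(15, seed), eco)
    expect_true(all(v$wsa <= v$area_ha + 1e-12))
    ppi <- eco$ppi[match(v$ecotype, eco$name)]
    expect_true(all(v$pwsa <= ppi * v$area_ha + 1e-12))
  }
})
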
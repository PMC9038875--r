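# small in-code fixtures shared across test files

# one terrestrial + one embayment parcel, step maturation with a 30-day lag
tiny_ledger <- function(lag_days = 30, schedule = "step") {
  service_area_ledger(
    name = "tiny",
    parcels = parcels(
      parcel_id = c("land1", "emb1"),
      ecotype = c("terrestrial", "embayment"),
      area_ha = c(10, 5), suitability = c(0, 0.5),
      zone = c("mainland", NA)),
    maturation = list(schedule = schedule, lag_days = lag_days))
}

# the worked single-trade scenario: 1 ha land -> wetland at `dep_suit`,
# deposit matured, then a 1-ha embayment withdrawal at `emb_suit`
worked_ledger <- function(dep_suit = 0.75, emb_suit = 0.5) {
  l <- service_area_ledger(
    name = "worked",
    parcels = parcels(
      parcel_id = c("land1", "emb1"),
      ecotype = c("terrestrial", "embayment"),
      area_ha = c(10, 5), suitability = c(0, emb_suit),
      zone = c("mainland", NA)),
    maturation = list(schedule = "step", lag_days = 30))
  l <- record_deposit(
    l, created = parcels("wet.dep", "wetland", 1, dep_suit),
    from = data.frame(parcel_id = "land1", area_ha = 1),
    date = as.Date("2024-01-01"))
  record_withdrawal(
    l, impacted = data.frame(parcel_id = "emb1", area_ha = 1),
    date = as.Date("2024-03-01"), post_zone = "mainland")
}

# deterministic random inventory of scalar-suitability parcels
random_parcels <- function(n, seed) {
  withr::with_seed(seed, {
    eco <- sample(c("rivermouth", "wetland", "embayment", "open_coast",
                    "offshore", "terrestrial"), n, replace = TRUE)
    parcels(
      parcel_id = sprintf("p%03d", seq_len(n)), ecotype = eco,
      area_ha = round(runif(n, 0.1, 50), 3),
      suitability = ifelse(eco == "terrestrial", 0, round(runif(n), 3)))
  })
}

# independent brute-force oracle: per-parcel loop, guild combination done
# inline, no calls into the rollup under test
oracle_totals <- function(p, ecotypes, weights) {
  tot_wsa <- 0
  tot_pwsa <- 0
  for (i in seq_len(nrow(p))) {
    if (p$status[i] == "retired") next
    m <- p$suit_map[[i]]
    s <- if (is.null(m)) {
      p$suitability[i]
    } else {
      acc <- 0
      for (k in names(m)) acc <- acc + weights[k, p$ecotype[i]] / 100 * m[[k]]
      acc
    }
    ppi <- ecotypes$ppi[ecotypes$name == p$ecotype[i]]
    tot_wsa <- tot_wsa + p$area_ha[i] * s
    tot_pwsa <- tot_pwsa + p$area_ha[i] * s * ppi
  }
  list(wsa = tot_wsa, pwsa = tot_pwsa)
}
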
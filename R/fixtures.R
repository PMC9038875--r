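#' The packaged Toronto-nearshore worked example
#'
#' Builds the service-area ledger of the worked nearshore example: ecotype
#' areas 30 (rivermouth), 160 (wetland), 830 (embayment), 14,000 (open
#' coast) and 440 ha (offshore) plus 130 ha mainland and 80 ha islands of
#' terrestrial buffer; quality-class fractions High 60/80/50/65/50, Med
#' 10/15/40/25/30, Low 30/5/10/10/20 percent with representative
#' suitabilities 0.75 / 0.50 / 0.25; the default PPI table and guild weight
#' matrix; notional area objectives; and (optionally) the three-transaction
#' journal — a 1-ha land-to-wetland deposit, a 1-ha embayment infill
#' withdrawal, and the equivalency trade between them at offset ratio 1.
#'
#' The inventory is the coarsest one reproducing the published baseline:
#' one parcel per (ecotype, quality class). With `unit_suitability = TRUE`
#' every aquatic parcel is instead held at suitability 1.0 (one parcel per
#' ecotype), which is the variant behind the supply balance sheet whose
#' baseline totals 8305 PWSA and updates to 8306 after the trade.
#'
#' @param unit_suitability Use the unit-suitability variant (default FALSE:
#'   quality-class suitabilities).
#' @param include_journal Record the worked deposit / withdrawal / trade
#'   journal (default TRUE).
#' @return A `service_area_ledger`.
#' @export
make_toronto_fixture <- function(unit_suitability = FALSE,
                                 include_journal = TRUE) {
  areas <- c(rivermouth = 30, wetland = 160, embayment = 830,
             open_coast = 14000, offshore = 440)
  frac <- rbind(High = c(60, 80, 50, 65, 50),
                Med = c(10, 15, 40, 25, 30),
                Low = c(30, 5, 10, 10, 20))
  colnames(frac) <- names(areas)
  suits <- c(High = 0.75, Med = 0.50, Low = 0.25)

  terr <- parcels(
    parcel_id = c("terr.mainland", "terr.islands"),
    ecotype = "terrestrial", area_ha = c(130, 80), suitability = 0,
    zone = c("mainland", "islands"), provenance = "natural")

  if (unit_suitability) {
    aq <- parcels(
      parcel_id = names(areas), ecotype = names(areas),
      area_ha = unname(areas), suitability = 1, provenance = "natural")
  } else {
    rows <- expand.grid(class = rownames(frac), ecotype = names(areas),
                        stringsAsFactors = FALSE)
    aq <- parcels(
      parcel_id = paste(rows$ecotype, tolower(rows$class), sep = "."),
      ecotype = rows$ecotype,
      area_ha = mapply(function(e, cl) areas[e] * frac[cl, e] / 100,
                       rows$ecotype, rows$class),
      suitability = suits[rows$class],
      provenance = "natural")
  }

  objectives <- objective_set(
    column = c("mainland", "islands", "rivermouth", "wetland", "embayment",
               "open_coast", "offshore"),
    target_ha = c(157, 157, 78, 784, 1567, 12426, 439),
    target_pct = c(1.0, 1.0, 0.5, 5.0, 10.0, 79.3, 2.8))

  ledger <- service_area_ledger(
    name = "toronto-nearshore",
    parcels = bind_parcels(terr, aq),
    objectives = objectives,
    boundary_metadata = paste(
      "Toronto region nearshore integrated planning area;",
      "terrestrial buffer between the 44 m and 77 m ASL elevation limits"),
    offset_ratio = 1,
    maturation = list(schedule = "step", lag_days = 365))

  if (include_journal) {
    dep_suit <- if (unit_suitability) 1 else 0.75
    wd_target <- if (unit_suitability) "embayment" else "embayment.med"
    ledger <- record_deposit(
      ledger,
      created = parcels(parcel_id = "wetland.dep1", ecotype = "wetland",
                        area_ha = 1, suitability = dep_suit,
                        provenance = "created"),
      from = data.frame(parcel_id = "terr.mainland", area_ha = 1),
      date = as.Date("2024-06-01"), maturity_days = 365, schedule = "step",
      cost_note = "construction and monitoring costed separately")
    ledger <- record_withdrawal(
      ledger,
      impacted = data.frame(parcel_id = wd_target, area_ha = 1),
      date = as.Date("2025-06-15"), post_zone = "mainland",
      cost_note = "proponent pays offset costs")
    ledger <- execute_trade(
      ledger, withdrawal = last_transaction(ledger)$txn_id,
      offset_ratio = 1, date = as.Date("2025-07-01"))
  }
  ledger
}

#' Parameters for the synthetic service-area generator
#'
#' @param seed Integer seed; one explicit pseudo-random stream drives the
#'   whole generation.
#' @param areas Named numeric vector of total hectares per ecotype
#'   (aquatic labels, optionally `terrestrial`).
#' @param n_parcels Parcels per ecotype (single integer or named vector).
#' @param suitability Either `list(type = "classes", fractions = c(High=,
#'   Med=, Low=))` (fractions sum to 1) or `list(type = "beta", shape1=,
#'   shape2=)`.
#' @param reserve_fraction Fraction of aquatic parcels marked reserve.
#' @param n_transactions Number of journal transactions to simulate
#'   (deposit / withdrawal / trade cycles).
#' @return A list of class `fixture_params`.
#' @export
fixture_params <- function(seed = 1L,
                           areas = c(terrestrial = 200, rivermouth = 30,
                                     wetland = 160, embayment = 830,
                                     open_coast = 14000, offshore = 440),
                           n_parcels = 5L,
                           suitability = list(type = "classes",
                                              fractions = c(High = 0.5,
                                                            Med = 0.3,
                                                            Low = 0.2)),
                           reserve_fraction = 0,
                           n_transactions = 0L) {
  if (identical(suitability$type, "classes")) {
    f <- suitability$fractions
    if (any(f < 0) || abs(sum(f) - 1) > 1e-9) {
      stop("class fractions must be in [0, 1] and sum to 1")
    }
  }
  if (reserve_fraction < 0 || reserve_fraction > 1) {
    stop("reserve_fraction must be in [0, 1]")
  }
  if (any(areas < 0)) stop("ecotype areas must be >= 0")
  structure(list(seed = as.integer(seed), areas = areas,
                 n_parcels = n_parcels, suitability = suitability,
                 reserve_fraction = reserve_fraction,
                 n_transactions = as.integer(n_transactions)),
            class = "fixture_params")
}

with_local_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic service-area ledger
#'
#' Deterministic for a given seed. Ecotype areas are split into the
#' requested number of parcels by normalised exponential spacings (so
#' realised totals match the requested ones exactly up to floating point);
#' suitabilities are drawn from the configured class fractions or Beta
#' distribution; a fraction of aquatic parcels can be pre-reserved; and an
#' optional journal of deposit / withdrawal / trade cycles is simulated.
#'
#' @param params A [fixture_params()].
#' @return A valid `service_area_ledger`.
#' @export
generate_service_area <- function(params) {
  stopifnot(inherits(params, "fixture_params"))
  with_local_seed(params$seed, {
    np <- params$n_parcels
    rows <- list()
    for (eco in names(params$areas)) {
      total <- params$areas[[eco]]
      if (total == 0) next
      n <- if (length(np) > 1) np[[eco]] else np
      if (n < 1) stop("cannot allocate positive area '", eco,
                      "' over zero parcels")
      w <- stats::rexp(n)
      a <- total * w / sum(w)
      if (eco == "terrestrial") {
        s <- rep(0, n)
      } else if (identical(params$suitability$type, "beta")) {
        s <- stats::rbeta(n, params$suitability$shape1,
                          params$suitability$shape2)
      } else {
        f <- params$suitability$fractions
        cls <- sample(names(f), n, replace = TRUE, prob = f)
        s <- quality_class_value(cls)
      }
      rows[[eco]] <- parcels(
        parcel_id = sprintf("%s.%03d", eco, seq_len(n)), ecotype = eco,
        area_ha = a, suitability = s,
        zone = if (eco == "terrestrial") "mainland" else NA_character_,
        provenance = "synthetic")
    }
    inv <- do.call(bind_parcels, rows)
    aquatic <- which(inv$ecotype != "terrestrial")
    n_res <- floor(params$reserve_fraction * length(aquatic))
    if (n_res > 0) {
      inv$status[sample(aquatic, n_res)] <- "reserve"
    }
    ledger <- service_area_ledger(
      name = sprintf("synthetic-%d", params$seed), parcels = inv,
      maturation = list(schedule = "step", lag_days = 30))

    day <- as.Date("2024-01-01")
    k <- 0
    while (k < params$n_transactions) {
      p <- ledger$parcels
      terr <- which(p$ecotype == "terrestrial" & p$status == "tradable" &
                      p$area_ha > 0.2)
      aq <- which(p$ecotype != "terrestrial" & p$status == "tradable" &
                    is.na(p$deposit_txn) & p$area_ha > 0.2)
      if (!length(terr) || !length(aq)) break
      # one cycle: deposit, withdrawal, then the offsetting trade
      src <- sample(terr, 1)
      dep_area <- min(1, p$area_ha[src] / 2)
      ledger <- record_deposit(
        ledger,
        created = parcels(parcel_id = sprintf("dep.%03d", k + 1L),
                          ecotype = "wetland", area_ha = dep_area,
                          suitability = stats::runif(1, 0.5, 1),
                          provenance = "created"),
        from = data.frame(parcel_id = p$parcel_id[src], area_ha = dep_area),
        date = day, maturity_days = 30)
      k <- k + 1
      if (k >= params$n_transactions) break
      tgt <- sample(aq, 1)
      dep_pwsa <- last_transaction(ledger)$pwsa_delta
      unit <- effective_suitability(ledger$parcels[tgt, , drop = FALSE],
                                    ledger$guild_weights) *
        ppi_of(ledger, ledger$parcels$ecotype[tgt])
      wd_area <- if (unit > 0) {
        min(ledger$parcels$area_ha[tgt] / 2, 0.9 * dep_pwsa / unit)
      } else {
        ledger$parcels$area_ha[tgt] / 2
      }
      if (wd_area <= AREA_TOL) break
      ledger <- record_withdrawal(
        ledger, impacted = data.frame(parcel_id = p$parcel_id[tgt],
                                      area_ha = wd_area),
        date = day + 40)
      k <- k + 1
      if (k >= params$n_transactions) break
      wd <- last_transaction(ledger)$txn_id
      if (last_transaction(ledger)$pwsa_delta < 0) {
        ledger <- execute_trade(ledger, withdrawal = wd, date = day + 50)
        k <- k + 1
      }
      day <- day + 60
    }
    ledger
  })
}
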
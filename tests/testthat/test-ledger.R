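test_that("deposits record the net PWSA gain of a land-to-water conversion", {
  l <- tiny_ledger()
  l <- record_deposit(
    l, created = parcels("wet.dep", "wetland", 1, 0.75),
    from = data.frame(parcel_id = "land1", area_ha = 1),
    date = as.Date("2024-01-01"))
  txn <- last_transaction(l)
  expect_equal(txn$pwsa_delta, 1.50)           # 1 ha * 0.75 * PPI 2.0
  expect_equal(l$accounts$full_pwsa, 1.50)
  # footprint conserved: land shrank by the created hectare
  expect_equal(l$parcels$area_ha[l$parcels$parcel_id == "land1"], 9)
  v <- valuation(l)
  expect_equal(attr(v, "total_area"), 15)

  l2 <- record_deposit(
    tiny_ledger(), created = parcels("wet.u", "wetland", 1, 1.0),
    from = data.frame(parcel_id = "land1", area_ha = 1),
    date = as.Date("2024-01-01"))
  expect_equal(last_transaction(l2)$pwsa_delta, 2.0)
})

test_that("degenerate or rule-breaking deposits are refused", {
  l <- tiny_ledger()
  expect_error(
    record_deposit(l, created = parcels("x", "wetland", 1, 0),
                   from = data.frame(parcel_id = "land1", area_ha = 1),
                   date = as.Date("2024-01-01")),
    "positive net PWSA gain")
  expect_error(
    record_deposit(l, created = parcels("x", "wetland", 2, 0.75),
                   from = data.frame(parcel_id = "land1", area_ha = 1),
                   date = as.Date("2024-01-01")),
    "conserve area")
  lr <- reserve_parcel(l, "land1", "protected", date = as.Date("2024-01-01"))
  expect_error(
    record_deposit(lr, created = parcels("x", "wetland", 1, 0.75),
                   from = data.frame(parcel_id = "land1", area_ha = 1),
                   date = as.Date("2024-01-02")),
    "reserve")
})

test_that("deposit value matures per schedule before it can be used", {
  mk <- function(schedule) {
    l <- tiny_ledger(lag_days = 100, schedule = schedule)
    record_deposit(l, created = parcels("wet.dep", "wetland", 1, 0.75),
                   from = data.frame(parcel_id = "land1", area_ha = 1),
                   date = as.Date("2024-01-01"))
  }
  step <- mk("step")
  acct <- step$accounts[1, ]
  expect_equal(available_value(acct, as.Date("2024-02-01")), 0)
  expect_equal(available_value(acct, as.Date("2024-04-10")), 1.50)
  expect_error(available_value(acct, as.Date("2023-12-31")),
               "precedes the deposit date")

  lin <- mk("linear")$accounts[1, ]
  expect_equal(available_value(lin, as.Date("2024-01-01") + 50), 0.75)
  expect_equal(available_value(lin, as.Date("2024-01-01") + 100), 1.50)

  # matured deposit with 0.50 already committed leaves 1.00
  acct$committed_pwsa <- 0.50
  expect_equal(available_value(acct, as.Date("2024-06-01")), 1.00)
})

test_that("withdrawals record losses and refuse gains and reserves", {
  l <- tiny_ledger()
  l <- record_withdrawal(l, impacted = data.frame(parcel_id = "emb1",
                                                  area_ha = 1),
                         date = as.Date("2024-01-01"))
  expect_equal(last_transaction(l)$pwsa_delta, -0.50)
  expect_equal(attr(valuation(l), "total_area"), 15)  # infill conserves ha

  lu <- service_area_ledger(
    "u", parcels = parcels("emb1", "embayment", 5, 1.0))
  lu <- record_withdrawal(lu, impacted = data.frame(parcel_id = "emb1",
                                                    area_ha = 1),
                          date = as.Date("2024-01-01"))
  expect_equal(last_transaction(lu)$pwsa_delta, -1.0)

  lr <- reserve_parcel(tiny_ledger(), "emb1", "protected",
                       date = as.Date("2024-01-01"))
  expect_error(
    record_withdrawal(lr, impacted = data.frame(parcel_id = "emb1",
                                                area_ha = 1),
                      date = as.Date("2024-01-02")),
    "reserve")

  # an upgrade is a deposit, not a withdrawal
  expect_error(
    record_withdrawal(tiny_ledger(),
                      impacted = data.frame(parcel_id = "emb1", area_ha = 1),
                      date = as.Date("2024-01-01"),
                      post_ecotype = "wetland", post_suitability = 1),
    "deposit instead")
})

test_that("offset solver inverts the valuation identity", {
  expect_equal(solve_offset(0.50, 0.75, 2.0), 1 / 3)
  expect_equal(solve_offset(1.0, 1.0, 2.0), 0.5)
  expect_equal(solve_offset(0.50, 0.5, 0.5, offset_ratio = 2), 4.0)
  expect_error(solve_offset(0.5, 0, 2), "zero-productivity")
  expect_error(solve_offset(-1, 0.5, 1), "loss_pwsa")
  expect_error(solve_offset(1, 0.5, 1, offset_ratio = 0.5), ">= 1")

  # inverse property across random cases
  withr::with_seed(42, {
    for (k in 1:20) {
      loss <- runif(1, 0.01, 10)
      s <- runif(1, 0.05, 1)
      ppi <- runif(1, 0.1, 3)
      r <- 1 + runif(1, 0, 2)
      area <- solve_offset(loss, s, ppi, r)
      expect_equal(area * s * ppi, r * loss, tolerance = 1e-9)
    }
  })
})

test_that("the worked trade nets to zero and leaves a 1.00 PWSA remainder", {
  l <- worked_ledger()              # deposit +1.50, withdrawal -0.50
  wd <- last_transaction(l)$txn_id
  l <- execute_trade(l, withdrawal = wd, date = as.Date("2024-06-01"))
  res <- trade_resolution(l)
  expect_equal(sum(res$area_used), 1 / 3, tolerance = 1e-9)
  expect_equal(sum(res$pwsa_used), 0.50, tolerance = 1e-9)
  expect_equal(attr(res, "net_pwsa"), 0, tolerance = 1e-9)
  expect_equal(l$accounts$full_pwsa - l$accounts$committed_pwsa, 1.00)
  # the used portion joined the natural capital reserves
  used <- l$parcels[l$parcels$provenance %in% "traded deposit portion", ]
  expect_equal(used$status, "reserve")
  expect_equal(used$area_ha, 1 / 3, tolerance = 1e-9)
})

test_that("trades respect holds, coverage and single-offset rules", {
  l <- worked_ledger()
  wd <- last_transaction(l)$txn_id
  # before maturity the step-schedule hold blocks the trade
  expect_error(execute_trade(l, withdrawal = wd, date = as.Date("2024-01-15")),
               "insufficient matured")
  l2 <- execute_trade(l, withdrawal = wd, date = as.Date("2024-06-01"))
  expect_error(execute_trade(l2, withdrawal = wd,
                             date = as.Date("2024-06-02")),
               "already offset")
  expect_error(execute_trade(l, withdrawal = "T0001",
                             date = as.Date("2024-06-01")),
               "not a recorded withdrawal")
})

test_that("offset ratios scale the debit and stay fully covered", {
  l <- worked_ledger()
  wd <- last_transaction(l)$txn_id
  l <- execute_trade(l, withdrawal = wd, offset_ratio = 2,
                     date = as.Date("2024-06-01"))
  res <- trade_resolution(l)
  expect_equal(sum(res$pwsa_used), 2 * 0.50, tolerance = 1e-9)
  expect_equal(sum(res$area_used), solve_offset(0.5, 0.75, 2, 2),
               tolerance = 1e-9)
  expect_equal(l$accounts$committed_pwsa, 1.0)
})

test_that("multi-deposit trades debit FIFO by maturity date", {
  l <- tiny_ledger(lag_days = 10)
  l <- record_deposit(l, created = parcels("dep.late", "wetland", 1, 0.5),
                      from = data.frame(parcel_id = "land1", area_ha = 1),
                      date = as.Date("2024-01-01"), maturity_days = 200)
  l <- record_deposit(l, created = parcels("dep.early", "wetland", 1, 0.5),
                      from = data.frame(parcel_id = "land1", area_ha = 1),
                      date = as.Date("2024-01-02"), maturity_days = 10)
  l <- record_withdrawal(l, impacted = data.frame(parcel_id = "emb1",
                                                  area_ha = 1),
                         date = as.Date("2024-12-01"))
  wd <- last_transaction(l)$txn_id
  l <- execute_trade(l, withdrawal = wd, date = as.Date("2024-12-31"))
  res <- trade_resolution(l)
  # earliest-maturing deposit (the second txn) is debited first
  expect_equal(res$deposit_txn[1], "T0002")
  expect_equal(res$parcel_id[1], "dep.early")
})

test_that("reservations are protective, idempotent and monotone", {
  l <- tiny_ledger()
  l <- reserve_parcel(l, "emb1", "high quality", date = as.Date("2024-01-01"))
  expect_equal(l$parcels$status[l$parcels$parcel_id == "emb1"], "reserve")
  expect_error(
    record_withdrawal(l, impacted = data.frame(parcel_id = "emb1",
                                               area_ha = 1),
                      date = as.Date("2024-01-02")),
    "reserve")
  # idempotent no-op is still journalled
  l2 <- reserve_parcel(l, "emb1", "again", date = as.Date("2024-01-03"))
  expect_equal(nrow(l2$journal), 2)
  expect_equal(l2$parcels$status[l2$parcels$parcel_id == "emb1"], "reserve")
  expect_error(reserve_parcel(worked_ledger(), "T0002.post", date =
                                as.Date("2024-03-02")), NA)
})

test_that("reserve set only grows across a full transaction history", {
  l <- make_toronto_fixture()
  st <- l
  st$parcels <- l$baseline_parcels
  st$accounts <- habbank:::empty_accounts()
  reserved <- character(0)
  for (i in seq_len(nrow(l$journal))) {
    st <- habbank:::apply_ops(st, l$journal$detail[[i]]$ops)
    now <- st$parcels$parcel_id[st$parcels$status == "reserve"]
    expect_true(all(reserved %in% now))
    reserved <- now
  }
})

test_that("transfers move banked value between ledgers with a warning flag", {
  a <- worked_ledger()
  a <- execute_trade(a, withdrawal = last_transaction(a)$txn_id,
                     date = as.Date("2024-06-01"))  # leaves 1.00 banked
  b <- service_area_ledger("other-area")
  res <- record_transfer(a, b, pwsa = 1.0,
                         justification = "no local restoration potential",
                         date = as.Date("2024-07-01"))
  expect_equal(bank_balance(res$from, as.Date("2024-07-01")), 0)
  expect_equal(bank_balance(res$to, as.Date("2024-07-01")), 1.0)
  out <- last_transaction(res$from)
  inn <- last_transaction(res$to)
  expect_true(out$warning_flag && inn$warning_flag)
  expect_equal(out$detail[[1]]$counterpart_txn, inn$txn_id)
  expect_equal(inn$detail[[1]]$counterpart_ledger, "worked")

  expect_error(record_transfer(a, b, pwsa = 0, justification = "x",
                               date = as.Date("2024-07-01")), "> 0")
  expect_error(record_transfer(a, b, pwsa = 0.5, justification = "",
                               date = as.Date("2024-07-01")),
               "justification")
  expect_error(record_transfer(a, b, pwsa = 99, justification = "too much",
                               date = as.Date("2024-07-01")),
               "insufficient")
})

test_that("area is conserved by every non-transfer transaction", {
  l <- make_toronto_fixture()
  st <- l
  st$parcels <- l$baseline_parcels
  st$accounts <- habbank:::empty_accounts()
  total0 <- sum(habbank:::active_parcels(st$parcels)$area_ha)
  for (i in seq_len(nrow(l$journal))) {
    st <- habbank:::apply_ops(st, l$journal$detail[[i]]$ops)
    expect_equal(sum(habbank:::active_parcels(st$parcels)$area_ha), total0)
  }
})

test_that("no deposit is debited past maturity and commitments never shrink", {
  params <- fixture_params(seed = 11, n_transactions = 9)
  l <- generate_service_area(params)
  for (i in seq_len(nrow(l$accounts))) {
    acct <- l$accounts[i, ]
    expect_lte(acct$committed_pwsa, acct$full_pwsa + 1e-9)
    expect_gte(acct$committed_pwsa, 0)
  }
  # double-entry: each trade's debits equal r times the withdrawal loss
  j <- l$journal
  for (i in which(j$kind == "trade")) {
    res <- trade_resolution(l, j$txn_id[i])
    loss <- -j$pwsa_delta[j$txn_id == attr(res, "withdrawal")]
    expect_equal(sum(res$pwsa_used), attr(res, "offset_ratio") * loss,
                 tolerance = 1e-9)
  }
})

test_that("replay reproduces current state deterministically", {
  for (l in list(make_toronto_fixture(),
                 make_toronto_fixture(unit_suitability = TRUE),
                 generate_service_area(fixture_params(seed = 3,
                                                      n_transactions = 6)))) {
    v_now <- valuation(l)
    v_rep <- replay(l)
    expect_equal(v_rep$pwsa, v_now$pwsa)
    expect_equal(v_rep$area_ha, v_now$area_ha)
    expect_equal(replay(l)$pwsa, v_rep$pwsa)  # idempotent
  }
  empty <- service_area_ledger("e", parcels = parcels("p", "wetland", 2, 0.5))
  expect_equal(replay(empty)$pwsa, valuation(empty)$pwsa)
})
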
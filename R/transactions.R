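`%||%` <- function(a, b) if (is.null(a)) b else a

AREA_TOL <- 1e-9

# ---- primitive journal operations -----------------------------------------
# Every transaction is recorded as a list of primitive ops; replay() applies
# the same ops from the baseline, so recording and replaying share one code
# path and cannot drift apart.
#   shrink(id, by)   reduce a parcel's area; a full shrink retires it
#   add(parcel)      append a parcel row
#   status(id, to)   change trading status
#   account_open(txn_id, full_pwsa, deposit_date, maturity_date, schedule)
#   account_debit(txn_id, amount)

apply_ops <- function(ledger, ops) {
  for (op in ops) {
    ledger <- switch(op$op,
      shrink = {
        i <- match(op$id, ledger$parcels$parcel_id)
        if (is.na(i)) stop("replay: unknown parcel '", op$id, "'")
        if (op$by >= ledger$parcels$area_ha[i] - AREA_TOL) {
          ledger$parcels$status[i] <- "retired"
        } else {
          ledger$parcels$area_ha[i] <- ledger$parcels$area_ha[i] - op$by
        }
        ledger
      },
      add = {
        row <- op$parcel
        ledger$parcels <- bind_parcels(ledger$parcels, parcels(
          parcel_id = row$parcel_id, ecotype = row$ecotype,
          area_ha = row$area_ha,
          suitability = row$suitability %||% NA_real_,
          suit_map = list(if (is.null(row$suit_map)) NULL else unlist(row$suit_map)),
          status = row$status %||% "tradable",
          zone = row$zone %||% NA_character_,
          provenance = row$provenance %||% NA_character_,
          deposit_txn = row$deposit_txn %||% NA_character_))
        ledger
      },
      status = {
        i <- match(op$id, ledger$parcels$parcel_id)
        if (is.na(i)) stop("replay: unknown parcel '", op$id, "'")
        ledger$parcels$status[i] <- op$to
        ledger
      },
      account_open = {
        ledger$accounts <- dplyr::bind_rows(ledger$accounts, tibble::tibble(
          txn_id = op$txn_id, full_pwsa = op$full_pwsa, committed_pwsa = 0,
          deposit_date = as.Date(op$deposit_date),
          maturity_date = as.Date(op$maturity_date), schedule = op$schedule))
        ledger
      },
      account_debit = {
        i <- match(op$txn_id, ledger$accounts$txn_id)
        if (is.na(i)) stop("replay: unknown deposit account '", op$txn_id, "'")
        ledger$accounts$committed_pwsa[i] <-
          ledger$accounts$committed_pwsa[i] + op$amount
        ledger
      },
      stop("unknown journal op '", op$op, "'")
    )
  }
  ledger
}

append_txn <- function(ledger, kind, date, pwsa_delta, ops, detail = list(),
                       offset_ratio = NA_real_, maturity_date = as.Date(NA),
                       schedule = NA_character_, justification = NA_character_,
                       cost_note = NA_character_, warning_flag = FALSE) {
  txn_id <- next_txn_id(ledger)
  date <- as.Date(date)
  if (nrow(ledger$journal) > 0) {
    lastd <- ledger$journal$date[nrow(ledger$journal)]
    if (date < lastd) {
      stop("journal is append-only: transaction date ", format(date),
           " precedes the last entry (", format(lastd), ")")
    }
  }
  detail$ops <- ops
  row <- tibble::tibble(
    txn_id = txn_id, kind = kind, date = date, pwsa_delta = pwsa_delta,
    offset_ratio = offset_ratio, maturity_date = as.Date(maturity_date),
    schedule = schedule, justification = justification, cost_note = cost_note,
    warning_flag = warning_flag, detail = list(detail))
  ledger$journal <- dplyr::bind_rows(ledger$journal, row)
  apply_ops(ledger, ops)
}

# normalise a footprint spec: character ids (full parcel area) or a data
# frame with parcel_id and area_ha columns
footprint_spec <- function(ledger, spec, verb) {
  p <- ledger$parcels
  if (is.character(spec)) {
    spec <- tibble::tibble(parcel_id = spec, area_ha = NA_real_)
  }
  spec <- tibble::as_tibble(spec)
  i <- match(spec$parcel_id, p$parcel_id)
  if (anyNA(i)) {
    stop("cannot ", verb, " unknown parcel(s): ",
         paste(spec$parcel_id[is.na(i)], collapse = ", "))
  }
  st <- p$status[i]
  if (any(st == "reserve")) {
    stop("cannot ", verb, " reserve parcel(s): ",
         paste(spec$parcel_id[st == "reserve"], collapse = ", "),
         " (natural capital reserves are not available for trading)")
  }
  if (any(st == "retired")) {
    stop("cannot ", verb, " retired parcel(s): ",
         paste(spec$parcel_id[st == "retired"], collapse = ", "))
  }
  spec$area_ha <- ifelse(is.na(spec$area_ha), p$area_ha[i], spec$area_ha)
  over <- spec$area_ha > p$area_ha[i] + AREA_TOL
  if (any(over)) {
    stop("footprint exceeds parcel area for: ",
         paste(spec$parcel_id[over], collapse = ", "))
  }
  spec$row <- i
  spec
}

footprint_pwsa <- function(ledger, spec) {
  if (nrow(spec) == 0) return(0)
  s <- effective_suitabilities(ledger$parcels[spec$row, , drop = FALSE],
                               ledger$guild_weights)
  sum(spec$area_ha * s * ppi_of(ledger, ledger$parcels$ecotype[spec$row]))
}

parcel_row_as_list <- function(p, i) {
  list(parcel_id = p$parcel_id[i], ecotype = p$ecotype[i],
       zone = p$zone[i], area_ha = p$area_ha[i],
       suitability = p$suitability[i],
       suit_map = if (is.null(p$suit_map[[i]])) NULL else as.list(p$suit_map[[i]]),
       status = p$status[i], provenance = p$provenance[i],
       deposit_txn = p$deposit_txn[i])
}

# ---- deposits --------------------------------------------------------------

#' Record a habitat deposit
#'
#' A deposit creates or enhances habitat: new (`created`) parcels enter the
#' inventory, optionally replacing the footprint of existing tradable
#' parcels (`from`) that are converted — e.g. terrestrial land, whose
#' aquatic value is zero, turned into wetland. The transaction's PWSA delta
#' is the post-PWSA of the created parcels minus the pre-PWSA of the
#' converted footprint, and must be positive. A deposit account is opened
#' with that delta as its full value; the value matures under the ledger's
#' maturation schedule ("the cheque must clear") before it can be traded.
#'
#' @param ledger A `service_area_ledger`.
#' @param created A [parcels()] tibble of the new habitat parcels.
#' @param from Optional converted footprint: parcel ids (full area) or a
#'   data frame with `parcel_id`, `area_ha`. When given, its total area must
#'   equal the created area (conversions conserve hectares). Reserve or
#'   retired parcels cannot be converted.
#' @param date Transaction date.
#' @param maturity_days Days from `date` until full ecological function;
#'   default the ledger's maturation lag.
#' @param schedule Maturation schedule, `"step"` (no value until maturity)
#'   or `"linear"` (value ramps linearly to maturity).
#' @param cost_note Free-text financial note; stored, never computed on.
#' @return The updated ledger; the deposit is the last journal entry and its
#'   account is in `ledger$accounts`.
#' @export
record_deposit <- function(ledger, created, from = NULL, date,
                           maturity_days = NULL, schedule = NULL,
                           cost_note = NA_character_) {
  created <- as_parcels(created)
  bad <- validate_parcels(created, ledger$ecotypes$name)
  if (length(bad)) stop("created parcels invalid: ", paste(bad, collapse = "; "))
  if (any(created$parcel_id %in% ledger$parcels$parcel_id)) {
    stop("created parcel ids already present in the inventory")
  }
  pre <- 0
  ops <- list()
  if (!is.null(from)) {
    spec <- footprint_spec(ledger, from, "convert")
    if (abs(sum(spec$area_ha) - sum(created$area_ha)) > 1e-6) {
      stop("conversion must conserve area: footprint ",
           format(sum(spec$area_ha)), " ha vs created ",
           format(sum(created$area_ha)), " ha")
    }
    pre <- footprint_pwsa(ledger, spec)
    ops <- lapply(seq_len(nrow(spec)), function(k)
      list(op = "shrink", id = spec$parcel_id[k], by = spec$area_ha[k]))
  }
  txn_id <- next_txn_id(ledger)
  created$deposit_txn <- txn_id
  created$status <- "tradable"
  post <- sum(created$area_ha *
                effective_suitabilities(created, ledger$guild_weights) *
                ppi_of(ledger, created$ecotype))
  delta <- post - pre
  if (delta <= 0) {
    stop("deposit must realise a positive net PWSA gain (got ",
         format(delta), ")")
  }
  date <- as.Date(date)
  maturity_days <- maturity_days %||% ledger$maturation$lag_days %||% 0
  schedule <- schedule %||% ledger$maturation$schedule %||% "step"
  stopifnot(schedule %in% c("step", "linear"))
  maturity_date <- date + maturity_days
  ops <- c(ops,
           lapply(seq_len(nrow(created)), function(k)
             list(op = "add", parcel = parcel_row_as_list(created, k))),
           list(list(op = "account_open", txn_id = txn_id, full_pwsa = delta,
                     deposit_date = format(date),
                     maturity_date = format(maturity_date),
                     schedule = schedule)))
  append_txn(ledger, "deposit", date, pwsa_delta = delta, ops = ops,
             detail = list(created = created$parcel_id,
                           from = if (is.null(from)) list() else
                             as.list(spec$parcel_id)),
             maturity_date = maturity_date, schedule = schedule,
             cost_note = cost_note)
}

# ---- maturation ------------------------------------------------------------

maturation_factor <- function(schedule, deposit_date, maturity_date, date) {
  if (schedule == "step") {
    return(as.numeric(date >= maturity_date))
  }
  span <- as.numeric(maturity_date - deposit_date)
  if (span <= 0) return(1)
  min(1, max(0, as.numeric(date - deposit_date) / span))
}

#' Matured, uncommitted value of a deposit account
#'
#' `full_pwsa * m(t) - committed_pwsa`, where `m(t)` is the maturation
#' schedule: a step (zero until the maturity date, then one — the deposit is
#' held "until the cheque clears") or a linear ramp from the deposit date to
#' maturity.
#'
#' @param account A one-row account tibble (a row of `ledger$accounts`), or
#'   a ledger together with `txn_id`.
#' @param date Valuation date; must not precede the deposit date.
#' @param txn_id Deposit transaction id when `account` is a ledger.
#' @return Available PWSA (>= 0).
#' @export
available_value <- function(account, date, txn_id = NULL) {
  if (inherits(account, "service_area_ledger")) {
    i <- match(txn_id, account$accounts$txn_id)
    if (is.na(i)) stop("no deposit account for txn '", txn_id, "'")
    account <- account$accounts[i, , drop = FALSE]
  }
  date <- as.Date(date)
  if (date < account$deposit_date) {
    stop("valuation date ", format(date), " precedes the deposit date ",
         format(account$deposit_date))
  }
  m <- maturation_factor(account$schedule, account$deposit_date,
                         account$maturity_date, date)
  max(0, account$full_pwsa * m - account$committed_pwsa)
}

#' Total matured, uncommitted bank balance of a ledger
#' @param ledger A ledger.
#' @param date Valuation date.
#' @return Sum of [available_value()] over all deposit accounts.
#' @export
bank_balance <- function(ledger, date) {
  a <- ledger$accounts
  if (nrow(a) == 0) return(0)
  sum(vapply(seq_len(nrow(a)), function(i)
    available_value(a[i, , drop = FALSE], date), numeric(1)))
}

# ---- withdrawals -----------------------------------------------------------

#' Record a habitat withdrawal
#'
#' A withdrawal is an unavoidable development impact: an aquatic footprint
#' is converted to a lower-valued post-state (by default terrestrial infill
#' at zero aquatic suitability). The PWSA delta is post minus pre and must
#' not be positive — a gain would be a deposit. Reserve parcels cannot be
#' impacted. The impacted footprint is retired (or shrunk) and the
#' post-state parcel enters the inventory, so total hectares are conserved.
#'
#' @param ledger A `service_area_ledger`.
#' @param impacted Impacted footprint: parcel ids (full area) or a data
#'   frame with `parcel_id`, `area_ha`.
#' @param date Transaction date.
#' @param post_ecotype Ecotype of the post-development state (default
#'   `terrestrial`).
#' @param post_suitability Suitability of the post state (default 0).
#' @param post_zone Reporting zone for the post-state parcel (e.g.
#'   `mainland` for an infill).
#' @param cost_note Free-text financial note.
#' @return The updated ledger; the withdrawal is the last journal entry.
#' @export
record_withdrawal <- function(ledger, impacted, date,
                              post_ecotype = "terrestrial",
                              post_suitability = 0, post_zone = NA_character_,
                              cost_note = NA_character_) {
  spec <- footprint_spec(ledger, impacted, "withdraw")
  pre <- footprint_pwsa(ledger, spec)
  txn_id <- next_txn_id(ledger)
  post_area <- sum(spec$area_ha)
  post <- post_area * post_suitability * ppi_of(ledger, post_ecotype)
  delta <- post - pre
  if (delta > 0) {
    stop("withdrawal must not increase PWSA (got +", format(delta),
         "); record a deposit instead")
  }
  post_parcel <- parcels(
    parcel_id = paste0(txn_id, ".post"), ecotype = post_ecotype,
    area_ha = post_area, suitability = post_suitability, zone = post_zone,
    provenance = "post-development")
  ops <- c(
    lapply(seq_len(nrow(spec)), function(k)
      list(op = "shrink", id = spec$parcel_id[k], by = spec$area_ha[k])),
    list(list(op = "add", parcel = parcel_row_as_list(post_parcel, 1))))
  append_txn(ledger, "withdrawal", date, pwsa_delta = delta, ops = ops,
             detail = list(impacted = as.list(spec$parcel_id),
                           post_parcel = paste0(txn_id, ".post")),
             cost_note = cost_note)
}

# ---- offset solver ---------------------------------------------------------

#' Solve the deposit area required to offset a PWSA loss
#'
#' Inverts the valuation identity `PWSA = area * S_eff * PPI`: the area of
#' deposit habitat needed to offset `loss_pwsa` at offset ratio `r` is
#' `r * loss_pwsa / (S_eff * PPI)`. Valuing the returned area reproduces
#' `r * loss_pwsa` exactly.
#'
#' @param loss_pwsa Positive PWSA magnitude of the loss.
#' @param suitability Effective suitability of the offsetting deposit
#'   habitat, in (0, 1].
#' @param ppi PPI of the deposit ecotype, > 0.
#' @param offset_ratio Multiplier `r >= 1` compensating for time lags and
#'   uncertainty; default 1 (no ratio).
#' @return Required area in hectares.
#' @export
solve_offset <- function(loss_pwsa, suitability, ppi, offset_ratio = 1) {
  if (loss_pwsa <= 0) stop("loss_pwsa must be > 0")
  if (offset_ratio < 1) stop("offset_ratio must be >= 1")
  unit <- suitability * ppi
  if (unit <= 0) {
    stop("cannot offset with zero-productivity habitat (suitability * PPI = 0)")
  }
  offset_ratio * loss_pwsa / unit
}

# ---- trades ----------------------------------------------------------------

# debit `amount` PWSA from matured deposit accounts, FIFO by maturity date
# then txn_id, reserving the used portions of the backing parcels.
debit_bank <- function(ledger, amount, date, accounts = NULL, verb = "trade") {
  acc <- ledger$accounts
  if (!is.null(accounts)) {
    miss <- setdiff(accounts, acc$txn_id)
    if (length(miss)) stop("no deposit account for: ", paste(miss, collapse = ", "))
    acc <- acc[acc$txn_id %in% accounts, , drop = FALSE]
  }
  acc <- acc[order(acc$maturity_date, acc$txn_id), , drop = FALSE]
  avail <- vapply(seq_len(nrow(acc)), function(i)
    available_value(acc[i, , drop = FALSE], date), numeric(1))
  if (sum(avail) + AREA_TOL < amount) {
    stop("insufficient matured deposit balance for ", verb, ": need ",
         format(amount), " PWSA, available ", format(sum(avail)),
         " (unmatured deposits are on hold)")
  }
  ops <- list()
  alloc <- list()
  remaining <- amount
  for (i in seq_len(nrow(acc))) {
    if (remaining <= AREA_TOL) break
    take <- min(avail[i], remaining)
    if (take <= AREA_TOL) next
    ops <- c(ops, list(list(op = "account_debit", txn_id = acc$txn_id[i],
                            amount = take)))
    # reserve the used portion of the parcels backing this deposit
    p <- ledger$parcels
    backing <- which(p$deposit_txn %in% acc$txn_id[i] & p$status == "tradable")
    backing <- backing[order(p$parcel_id[backing])]
    left <- take
    for (j in backing) {
      if (left <= AREA_TOL) break
      unit <- effective_suitability(p[j, , drop = FALSE], ledger$guild_weights) *
        ppi_of(ledger, p$ecotype[j])
      if (unit <= 0) next
      cap <- p$area_ha[j] * unit
      use_pwsa <- min(cap, left)
      use_area <- use_pwsa / unit
      if (use_area >= p$area_ha[j] - AREA_TOL) {
        ops <- c(ops, list(list(op = "status", id = p$parcel_id[j],
                                to = "reserve")))
        use_area <- p$area_ha[j]
        use_pwsa <- cap
      } else {
        part_id <- paste0(p$parcel_id[j], ".r",
                          sum(startsWith(p$parcel_id, paste0(p$parcel_id[j], ".r"))) + 1L)
        part <- parcels(parcel_id = part_id, ecotype = p$ecotype[j],
                        area_ha = use_area, suitability = p$suitability[j],
                        suit_map = p$suit_map[j], status = "reserve",
                        zone = p$zone[j], provenance = "traded deposit portion",
                        deposit_txn = p$deposit_txn[j])
        ops <- c(ops,
                 list(list(op = "shrink", id = p$parcel_id[j], by = use_area)),
                 list(list(op = "add", parcel = parcel_row_as_list(part, 1))))
      }
      alloc <- c(alloc, list(tibble::tibble(
        deposit_txn = acc$txn_id[i], parcel_id = p$parcel_id[j],
        area_used = use_area, pwsa_used = use_pwsa)))
      left <- left - use_pwsa
    }
    remaining <- remaining - take
  }
  list(ops = ops,
       allocations = if (length(alloc)) dplyr::bind_rows(alloc) else
         tibble::tibble(deposit_txn = character(), parcel_id = character(),
                        area_used = numeric(), pwsa_used = numeric()))
}

#' Execute an equivalency trade against a recorded withdrawal
#'
#' Debits matured deposit accounts (FIFO by maturity date, ties broken by
#' transaction id) for `r` times the withdrawal's PWSA loss and moves the
#' used portions of the deposit parcels into the natural-capital reserves,
#' where they are no longer available for offsetting. The trade nets to
#' zero by construction: debited PWSA equals `r` times the loss.
#'
#' @param ledger A `service_area_ledger`.
#' @param withdrawal Transaction id of a prior withdrawal not yet offset.
#' @param deposits Optional character vector restricting which deposit
#'   accounts may be debited; default all.
#' @param offset_ratio Ratio `r >= 1`; default the ledger's configured
#'   default (1).
#' @param date Trade date; deposits must be matured (per their schedule) by
#'   this date.
#' @return The updated ledger. The trade's allocation table is available via
#'   [trade_resolution()].
#' @export
execute_trade <- function(ledger, withdrawal, deposits = NULL,
                          offset_ratio = NULL, date) {
  j <- ledger$journal
  wi <- match(withdrawal, j$txn_id)
  if (is.na(wi) || j$kind[wi] != "withdrawal") {
    stop("'", withdrawal, "' is not a recorded withdrawal")
  }
  already <- vapply(seq_len(nrow(j)), function(i)
    j$kind[i] == "trade" &&
      identical(j$detail[[i]]$withdrawal, withdrawal), logical(1))
  if (any(already)) {
    stop("withdrawal '", withdrawal, "' is already offset by trade '",
         j$txn_id[which(already)[1]], "'")
  }
  loss <- -j$pwsa_delta[wi]
  if (loss <= 0) stop("withdrawal '", withdrawal, "' has no PWSA loss to offset")
  r <- offset_ratio %||% ledger$offset_ratio %||% 1
  if (r < 1) stop("offset_ratio must be >= 1")
  need <- r * loss
  deb <- debit_bank(ledger, need, as.Date(date), accounts = deposits)
  net <- sum(deb$allocations$pwsa_used) - need
  append_txn(ledger, "trade", date, pwsa_delta = 0, ops = deb$ops,
             detail = list(withdrawal = withdrawal,
                           allocations = lapply(
                             seq_len(nrow(deb$allocations)), function(k)
                               as.list(deb$allocations[k, , drop = FALSE])),
                           net_pwsa = net),
             offset_ratio = r)
}

#' Allocation table of a recorded trade
#'
#' @param ledger A ledger.
#' @param txn_id Trade transaction id; default the most recent trade.
#' @return A tibble with one row per (deposit account, parcel) debit:
#'   `deposit_txn`, `parcel_id`, `area_used`, `pwsa_used`, plus attributes
#'   `withdrawal`, `offset_ratio` and `net_pwsa`.
#' @export
trade_resolution <- function(ledger, txn_id = NULL) {
  j <- ledger$journal
  trades <- which(j$kind == "trade")
  if (!length(trades)) stop("no trades recorded")
  i <- if (is.null(txn_id)) trades[length(trades)] else match(txn_id, j$txn_id)
  if (is.na(i) || j$kind[i] != "trade") stop("'", txn_id, "' is not a trade")
  d <- j$detail[[i]]
  out <- dplyr::bind_rows(lapply(d$allocations, tibble::as_tibble))
  attr(out, "withdrawal") <- d$withdrawal
  attr(out, "offset_ratio") <- j$offset_ratio[i]
  attr(out, "net_pwsa") <- d$net_pwsa
  out
}

# ---- reserves --------------------------------------------------------------

#' Set parcels aside as natural capital reserves
#'
#' Reserved parcels are protected: later conversions, withdrawals and trades
#' touching them fail. Reserving an already-reserved parcel is an idempotent
#' no-op (still journalled). Retired parcels cannot be reserved.
#'
#' @param ledger A `service_area_ledger`.
#' @param parcel_ids Character vector of parcel ids.
#' @param rationale Free-text justification.
#' @param date Transaction date.
#' @return The updated ledger.
#' @export
reserve_parcel <- function(ledger, parcel_ids, rationale = NA_character_,
                           date) {
  i <- match(parcel_ids, ledger$parcels$parcel_id)
  if (anyNA(i)) {
    stop("cannot reserve unknown parcel(s): ",
         paste(parcel_ids[is.na(i)], collapse = ", "))
  }
  st <- ledger$parcels$status[i]
  if (any(st == "retired")) {
    stop("cannot reserve retired parcel(s): ",
         paste(parcel_ids[st == "retired"], collapse = ", "))
  }
  todo <- parcel_ids[st == "tradable"]
  ops <- lapply(todo, function(id) list(op = "status", id = id, to = "reserve"))
  append_txn(ledger, "reservation", date, pwsa_delta = 0, ops = ops,
             detail = list(reserved = as.list(todo),
                           already_reserved = as.list(parcel_ids[st == "reserve"])),
             justification = rationale)
}

# ---- transfers -------------------------------------------------------------

#' Transfer banked PWSA between service areas
#'
#' An inter-area transfer debits matured, uncommitted deposit value from the
#' source ledger's bank (reserving the used deposit portions, exactly as a
#' trade does) and credits the target ledger with an immediately-available
#' external bank credit. Physical habitat does not move. Transfers are a
#' precautionary, last-resort instrument: both journal entries always carry
#' a warning flag, and a non-empty justification is mandatory.
#'
#' @param from_ledger Source `service_area_ledger`.
#' @param to_ledger Target `service_area_ledger`.
#' @param pwsa Positive PWSA amount to transfer.
#' @param justification Non-empty free text.
#' @param date Transaction date.
#' @return A list with the updated `from` and `to` ledgers; the paired
#'   journal entries reference each other.
#' @export
record_transfer <- function(from_ledger, to_ledger, pwsa, justification,
                            date) {
  if (!is.character(justification) || length(justification) != 1 ||
      is.na(justification) || !nzchar(trimws(justification))) {
    stop("inter-area transfers require a non-empty justification")
  }
  if (pwsa <= 0) stop("transfer amount must be > 0 PWSA")
  date <- as.Date(date)
  deb <- debit_bank(from_ledger, pwsa, date, verb = "transfer")
  out_id <- next_txn_id(from_ledger)
  in_id <- next_txn_id(to_ledger)
  from_ledger <- append_txn(
    from_ledger, "transfer_out", date, pwsa_delta = -pwsa, ops = deb$ops,
    detail = list(counterpart_ledger = to_ledger$name,
                  counterpart_txn = in_id,
                  allocations = lapply(seq_len(nrow(deb$allocations)),
                                       function(k) as.list(deb$allocations[k, , drop = FALSE]))),
    justification = justification, warning_flag = TRUE)
  to_ledger <- append_txn(
    to_ledger, "transfer_in", date, pwsa_delta = pwsa,
    ops = list(list(op = "account_open", txn_id = in_id, full_pwsa = pwsa,
                    deposit_date = format(date), maturity_date = format(date),
                    schedule = "step")),
    detail = list(counterpart_ledger = from_ledger$name,
                  counterpart_txn = out_id),
    justification = justification, warning_flag = TRUE)
  list(from = from_ledger, to = to_ledger)
}

# ---- replay ----------------------------------------------------------------

# rebuild ledger state (parcels + accounts) from the baseline by applying
# journal ops in order, up to and including `as_of` when given
replay_state <- function(ledger, as_of = NULL) {
  state <- ledger
  state$parcels <- ledger$baseline_parcels
  state$accounts <- empty_accounts()
  j <- ledger$journal
  keep <- if (is.null(as_of)) seq_len(nrow(j)) else which(j$date <= as.Date(as_of))
  for (i in keep) state <- apply_ops(state, j$detail[[i]]$ops)
  state
}

#' Replay the journal from the baseline inventory
#'
#' Applies every journal entry (optionally up to a date) to the baseline
#' parcel inventory and returns the resulting valuation. Replay is
#' deterministic and reproduces the ledger's current valuation exactly, so
#' supply accounts can be rebuilt from the journal at any time.
#'
#' @param ledger A `service_area_ledger`.
#' @param as_of Optional cut-off date (inclusive).
#' @return An `hb_valuation` tibble (see [valuation()]).
#' @export
replay <- function(ledger, as_of = NULL) {
  valuation(replay_state(ledger, as_of))
}
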
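empty_journal <- function() {
  tibble::tibble(
    txn_id = character(), kind = character(), date = as.Date(character()),
    pwsa_delta = numeric(), offset_ratio = numeric(),
    maturity_date = as.Date(character()), schedule = character(),
    justification = character(), cost_note = character(),
    warning_flag = logical(), detail = list()
  )
}

empty_accounts <- function() {
  tibble::tibble(
    txn_id = character(), full_pwsa = numeric(), committed_pwsa = numeric(),
    deposit_date = as.Date(character()), maturity_date = as.Date(character()),
    schedule = character()
  )
}

#' Create a service-area ledger
#'
#' The ledger is the bounded planning (service) area: its ecotype/PPI table,
#' optional guild weight matrix, parcel inventory, objectives and an ordered,
#' append-only transaction journal. All transaction functions
#' ([record_deposit()], [record_withdrawal()], [execute_trade()],
#' [reserve_parcel()], [record_transfer()]) take a ledger and return an
#' updated copy; the baseline inventory is kept so the journal can be
#' replayed from scratch with [replay()].
#'
#' @param name Service-area name.
#' @param ecotypes Ecotype/PPI table, default [default_ecotypes()].
#' @param guild_weights Optional [guild_weight_table()]; default the packaged
#'   matrix.
#' @param parcels Baseline parcel inventory (a [parcels()] tibble).
#' @param objectives Optional [objective_set()].
#' @param boundary_metadata Free-text boundary description (stored only,
#'   never used in computation).
#' @param offset_ratio Default offset ratio for trades, >= 1.
#' @param maturation Default maturation: a list with `schedule` ("step" or
#'   "linear") and `lag_days` (days from construction to full ecological
#'   function).
#' @return An object of class `service_area_ledger`.
#' @export
service_area_ledger <- function(name,
                                ecotypes = default_ecotypes(),
                                guild_weights = default_guild_weights(),
                                parcels = habbank::parcels(),
                                objectives = NULL,
                                boundary_metadata = NULL,
                                offset_ratio = 1,
                                maturation = list(schedule = "step",
                                                  lag_days = 0)) {
  stopifnot(is.character(name), length(name) == 1)
  if (!is.null(guild_weights)) guild_weights <- guild_weight_table(unclass(guild_weights))
  ledger <- structure(list(
    name = name,
    boundary_metadata = boundary_metadata,
    ecotypes = ecotypes,
    guild_weights = guild_weights,
    baseline_parcels = parcels,
    parcels = parcels,
    objectives = objectives,
    offset_ratio = offset_ratio,
    maturation = maturation,
    journal = empty_journal(),
    accounts = empty_accounts()
  ), class = "service_area_ledger")
  ledger
}

#' Per-ecotype area objectives
#'
#' Targets may be given as hectares, percent of the service-area total, or
#' both. Notional objective rows are reported as given, never re-normalised.
#'
#' @param column Column label the target applies to: an aquatic ecotype or a
#'   terrestrial zone.
#' @param target_ha Target hectares (may be `NA`).
#' @param target_pct Target percent of total area in [0, 100] (may be `NA`).
#' @return A tibble of class `objective_set`.
#' @export
objective_set <- function(column, target_ha = NA_real_, target_pct = NA_real_) {
  n <- length(column)
  out <- tibble::tibble(
    column = as.character(column),
    target_ha = rep_len(as.numeric(target_ha), n),
    target_pct = rep_len(as.numeric(target_pct), n)
  )
  class(out) <- c("objective_set", class(out))
  out
}

#' Validate a ledger against all domain invariants
#'
#' Checks ecotype PPI non-negativity and name uniqueness, guild-weight
#' column sums, parcel bounds (area > 0, suitabilities in [0, 1], unique
#' ids, known ecotypes, known statuses), objective percent bounds, and
#' journal ordering. Validation reports, it never throws.
#'
#' @param ledger A [service_area_ledger()].
#' @return Character vector of violations; empty if the ledger is valid.
#'   Each violation names the offending entity and the broken rule.
#' @export
validate_ledger <- function(ledger) {
  bad <- character(0)
  eco <- ledger$ecotypes
  dup <- unique(eco$name[duplicated(eco$name)])
  if (length(dup)) bad <- c(bad, sprintf("ecotype '%s': duplicate name", dup))
  neg <- !is.na(eco$ppi) & eco$ppi < 0
  if (any(neg)) {
    bad <- c(bad, sprintf("ecotype '%s': ppi must be >= 0", eco$name[neg]))
  }
  if (!is.null(ledger$guild_weights)) {
    bad <- c(bad, validate_guild_weights(ledger$guild_weights))
  }
  bad <- c(bad, validate_parcels(ledger$parcels, eco$name))
  if (!is.null(ledger$objectives)) {
    pct <- ledger$objectives$target_pct
    off <- !is.na(pct) & (pct < 0 | pct > 100)
    if (any(off)) {
      bad <- c(bad, sprintf("objective '%s': percent outside [0, 100]",
                            ledger$objectives$column[off]))
    }
  }
  j <- ledger$journal
  if (nrow(j) > 1) {
    ord <- order(j$date, j$txn_id)
    if (!identical(ord, seq_len(nrow(j)))) {
      bad <- c(bad, "journal: entries out of (date, txn_id) order")
    }
  }
  dupt <- unique(j$txn_id[duplicated(j$txn_id)])
  if (length(dupt)) bad <- c(bad, sprintf("txn '%s': duplicate txn_id", dupt))
  bad
}

#' @export
print.service_area_ledger <- function(x, ...) {
  cat(sprintf("<service_area_ledger> %s\n", x$name))
  cat(sprintf("  ecotypes: %d | parcels: %d (%d active) | journal: %d txns\n",
              nrow(x$ecotypes), nrow(x$parcels),
              nrow(active_parcels(x$parcels)), nrow(x$journal)))
  v <- valuation(x)
  cat(sprintf("  total area %.1f ha | total PWSA %.2f\n",
              attr(v, "total_area"), attr(v, "total_pwsa")))
  invisible(x)
}

#' Return the most recent journal entry
#'
#' Convenience accessor: transaction-recording functions return the updated
#' ledger, and the transaction itself is the last journal row.
#'
#' @param ledger A ledger.
#' @return A one-row tibble, or `NULL` for an empty journal.
#' @export
last_transaction <- function(ledger) {
  j <- ledger$journal
  if (nrow(j) == 0) return(NULL)
  j[nrow(j), , drop = FALSE]
}

next_txn_id <- function(ledger) sprintf("T%04d", nrow(ledger$journal) + 1L)

ppi_of <- function(ledger, ecotype) {
  i <- match(ecotype, ledger$ecotypes$name)
  if (anyNA(i)) stop("unknown ecotype: ", paste(ecotype[is.na(i)], collapse = ", "))
  ledger$ecotypes$ppi[i]
}
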
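report_column <- function(p) {
  ifelse(p$ecotype == "terrestrial",
         ifelse(is.na(p$zone), "terrestrial", p$zone),
         p$ecotype)
}

column_order <- function(cols) {
  aquatic <- aquatic_labels()
  terr <- setdiff(cols, aquatic)
  pref <- c("mainland", "islands")
  terr <- c(intersect(pref, terr), sort(setdiff(terr, pref)))
  c(terr, intersect(aquatic, cols))
}

# per-column (terrestrial zones, then aquatic ecotypes) area and PWSA rollup
column_valuation <- function(p, ecotypes, weights = NULL) {
  p <- active_parcels(p)
  if (nrow(p) == 0) {
    return(tibble::tibble(column = character(), area_ha = numeric(),
                          pwsa = numeric()))
  }
  s <- effective_suitabilities(p, weights)
  tibble::tibble(
    column = report_column(p),
    area_ha = p$area_ha,
    pwsa = p$area_ha * s * ecotypes$ppi[match(p$ecotype, ecotypes$name)]) |>
    dplyr::group_by(column) |>
    dplyr::summarise(area_ha = sum(area_ha), pwsa = sum(pwsa),
                     .groups = "drop")
}

#' Habitat supply balance sheet
#'
#' Builds the service-area balance sheet at a date: the baseline supply row
#' (area and PWSA per reporting column), one delta row per transaction kind
#' in the journal, the bank remainder (matured, uncommitted deposit value
#' and the area of the still-tradable deposit parcels), and the updated
#' supply row. Columns are the terrestrial zones followed by the aquatic
#' ecotypes, plus a total. All rows reconcile exactly at full precision
#' (`updated = baseline + sum of deltas`); rounding happens only when the
#' sheet is printed (areas to 1 decimal, PWSA to 2).
#'
#' @param ledger A `service_area_ledger`.
#' @param date Sheet date; default the date of the last journal entry (or
#'   today for an empty journal).
#' @return An object of class `balance_sheet`: a list with `columns`, `date`
#'   and matrices `pwsa` and `area` (rows: baseline, one per transaction
#'   kind present, bank, updated; last column: total).
#' @export
balance_sheet <- function(ledger, date = NULL) {
  j <- ledger$journal
  if (is.null(date)) {
    date <- if (nrow(j)) max(j$date) else Sys.Date()
  }
  date <- as.Date(date)
  eco <- ledger$ecotypes
  w <- ledger$guild_weights

  base_val <- column_valuation(ledger$baseline_parcels, eco, w)
  keep <- which(j$date <= date)

  # delta per transaction = column valuation after minus before
  kinds <- c("deposit", "withdrawal", "trade", "reservation",
             "transfer_out", "transfer_in")
  deltas <- list()
  state <- ledger
  state$parcels <- ledger$baseline_parcels
  state$accounts <- empty_accounts()
  prev <- column_valuation(state$parcels, eco, w)
  for (i in keep) {
    state <- apply_ops(state, j$detail[[i]]$ops)
    cur <- column_valuation(state$parcels, eco, w)
    d <- dplyr::full_join(cur, prev, by = "column",
                          suffix = c("", ".prev"))
    d[is.na(d)] <- 0
    deltas[[length(deltas) + 1L]] <- tibble::tibble(
      kind = j$kind[i], column = d$column,
      area_ha = d$area_ha - d$area_ha.prev, pwsa = d$pwsa - d$pwsa.prev)
    prev <- cur
  }
  updated_val <- prev

  cols <- column_order(unique(c(base_val$column, updated_val$column,
                                unlist(lapply(deltas, function(d) d$column)))))
  kinds_present <- intersect(kinds, j$kind[keep])
  rows <- c("baseline", kinds_present, "bank", "updated")
  get <- function(val, what) {
    out <- stats::setNames(rep(0, length(cols)), cols)
    out[val$column] <- val[[what]]
    out
  }
  pwsa <- matrix(0, nrow = length(rows), ncol = length(cols),
                 dimnames = list(rows, cols))
  area <- pwsa
  pwsa["baseline", ] <- get(base_val, "pwsa")
  area["baseline", ] <- get(base_val, "area_ha")
  for (k in kinds_present) {
    dk <- dplyr::bind_rows(deltas[vapply(deltas, function(d)
      d$kind[1] == k, logical(1))]) |>
      dplyr::group_by(column) |>
      dplyr::summarise(area_ha = sum(area_ha), pwsa = sum(pwsa),
                       .groups = "drop")
    pwsa[k, ] <- get(dk, "pwsa")
    area[k, ] <- get(dk, "area_ha")
  }

  # bank remainder: matured minus committed per account, placed in the
  # column of the deposit's backing parcels; area is the still-tradable
  # deposit parcel area
  acc <- state$accounts
  p <- active_parcels(state$parcels)
  for (i in seq_len(nrow(acc))) {
    if (acc$deposit_date[i] > date) next
    rem <- available_value(acc[i, , drop = FALSE], date)
    backing <- p[p$deposit_txn %in% acc$txn_id[i] & p$status == "tradable", ,
                 drop = FALSE]
    col <- if (nrow(backing)) report_column(backing)[1] else cols[1]
    pwsa["bank", col] <- pwsa["bank", col] + rem
    if (nrow(backing)) {
      bc <- report_column(backing)
      for (ci in unique(bc)) {
        area["bank", ci] <- area["bank", ci] +
          sum(backing$area_ha[bc == ci])
      }
    }
  }

  pwsa["updated", ] <- get(updated_val, "pwsa")
  area["updated", ] <- get(updated_val, "area_ha")
  pwsa <- cbind(pwsa, total = rowSums(pwsa))
  area <- cbind(area, total = rowSums(area))
  structure(list(columns = cols, date = date, pwsa = pwsa, area = area),
            class = "balance_sheet")
}

#' @export
print.balance_sheet <- function(x, ...) {
  cat(sprintf("Habitat supply balance sheet (as of %s)\n", format(x$date)))
  cat("PWSA (productivity-weighted suitable area, 2 dp):\n")
  print(round(x$pwsa, 2))
  cat("Area (ha, 1 dp):\n")
  print(round(x$area, 1))
  invisible(x)
}

#' Render a balance sheet as text, CSV or JSON
#'
#' Rendering rounds for display (areas 1 dp, PWSA 2 dp); the underlying
#' sheet stays at full precision and rounded output never feeds back into
#' computation.
#'
#' @param sheet A [balance_sheet()].
#' @param format One of `"text"`, `"csv"`, `"json"`.
#' @param path Optional file to write to; otherwise the rendering is
#'   returned as a character vector.
#' @return The rendering, invisibly when written to `path`.
#' @export
render_balance_sheet <- function(sheet, format = c("text", "csv", "json"),
                                 path = NULL) {
  format <- match.arg(format)
  out <- switch(format,
    text = utils::capture.output(print(sheet)),
    csv = {
      df <- data.frame(row = rownames(sheet$pwsa), measure = "pwsa",
                       round(sheet$pwsa, 2), check.names = FALSE)
      df2 <- data.frame(row = rownames(sheet$area), measure = "area_ha",
                        round(sheet$area, 1), check.names = FALSE)
      tc <- textConnection("csvout", "w", local = TRUE)
      utils::write.csv(rbind(df, df2), tc, row.names = FALSE)
      close(tc)
      csvout
    },
    json = jsonlite::toJSON(list(
      date = format(sheet$date), columns = colnames(sheet$pwsa),
      rows = rownames(sheet$pwsa),
      pwsa = round(unclass(sheet$pwsa), 6),
      area_ha = round(unclass(sheet$area), 6)),
      auto_unbox = TRUE, matrix = "rowmajor")
  )
  if (!is.null(path)) {
    writeLines(as.character(out), path)
    return(invisible(out))
  }
  out
}

#' Progress toward per-ecotype objectives
#'
#' Compares the current area per reporting column against the objective
#' table: absolute and percent gaps, and each column's share of the grand
#' total area (terrestrial included). Notional objectives are reported as
#' given; they are never re-normalised even when their entries do not sum
#' to the printed total.
#'
#' @param ledger A `service_area_ledger`.
#' @param objectives An [objective_set()]; default the ledger's.
#' @param date Optional valuation date (journal replayed up to it).
#' @return A tibble: `column`, `current_ha`, `pct_of_total`, `target_ha`,
#'   `target_pct`, `gap_ha`, `gap_pct`.
#' @export
progress_report <- function(ledger, objectives = NULL, date = NULL) {
  objectives <- objectives %||% ledger$objectives
  if (is.null(objectives) || nrow(objectives) == 0) {
    stop("no objectives configured")
  }
  state <- if (is.null(date)) ledger else replay_state(ledger, date)
  val <- column_valuation(state$parcels, ledger$ecotypes,
                          ledger$guild_weights)
  total <- sum(val$area_ha)
  out <- dplyr::left_join(objectives, val, by = "column")
  out$area_ha[is.na(out$area_ha)] <- 0
  tibble::tibble(
    column = out$column,
    current_ha = out$area_ha,
    pct_of_total = if (total > 0) 100 * out$area_ha / total else 0,
    target_ha = out$target_ha,
    target_pct = out$target_pct,
    gap_ha = out$target_ha - out$area_ha,
    gap_pct = out$target_pct - (if (total > 0) 100 * out$area_ha / total else 0)
  )
}
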
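suit_col_keys <- function() {
  keys <- guild_stage_keys()$keys
  stats::setNames(paste0("suit_", gsub(".", "_", keys, fixed = TRUE)), keys)
}

#' Read a parcel inventory from CSV or GeoJSON
#'
#' CSV dialect: comma-separated, decimal point, UTF-8; required columns
#' `parcel_id`, `ecotype`, `area_ha`, `status`, and either a `suitability`
#' column or the nine guild-resolved `suit_<guild>_<stage>` columns;
#' optional `zone` and `provenance`. GeoJSON: a FeatureCollection whose
#' features carry the same fields as properties, including an explicit
#' `area_ha` — geometry is provenance metadata only and is never used to
#' compute area.
#'
#' @param path File path.
#' @param format `"csv"` or `"geojson"`; guessed from the extension by
#'   default.
#' @return A validated [parcels()] inventory. All problems (missing
#'   columns, unknown ecotypes, duplicate ids, out-of-range values) are
#'   reported together with their row or feature index.
#' @export
read_parcels <- function(path, format = c("guess", "csv", "geojson")) {
  format <- match.arg(format)
  if (format == "guess") {
    format <- if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE))
      "geojson" else "csv"
  }
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
    unit <- "row"
  } else {
    gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    if (!identical(gj$type, "FeatureCollection")) {
      stop("GeoJSON must be a FeatureCollection")
    }
    props <- lapply(gj$features, function(f) f$properties)
    missing_area <- which(vapply(props, function(p)
      is.null(p$area_ha), logical(1)))
    if (length(missing_area)) {
      stop("GeoJSON feature(s) lacking the required 'area_ha' property: ",
           paste("feature", missing_area, collapse = ", "))
    }
    df <- dplyr::bind_rows(lapply(props, function(p)
      tibble::as_tibble(p[!vapply(p, is.null, logical(1))])))
    unit <- "feature"
  }
  required <- c("parcel_id", "ecotype", "area_ha", "status")
  miss <- setdiff(required, names(df))
  scols <- suit_col_keys()
  has_scalar <- "suitability" %in% names(df)
  has_map <- all(scols %in% names(df))
  if (!has_scalar && !has_map) {
    miss <- c(miss, "suitability (or the nine suit_<guild>_<stage> columns)")
  }
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  }
  suit_map <- vector("list", nrow(df))
  suitability <- rep(NA_real_, nrow(df))
  if (has_scalar) suitability <- as.numeric(df$suitability)
  if (has_map) {
    for (i in seq_len(nrow(df))) {
      vals <- as.numeric(df[i, scols])
      if (!anyNA(vals)) {
        suit_map[[i]] <- stats::setNames(vals, names(scols))
        suitability[i] <- NA_real_
      }
    }
  }
  p <- parcels(
    parcel_id = as.character(df$parcel_id), ecotype = as.character(df$ecotype),
    area_ha = as.numeric(df$area_ha), suitability = suitability,
    suit_map = suit_map, status = as.character(df$status),
    zone = if ("zone" %in% names(df)) as.character(df$zone) else NA_character_,
    provenance = if ("provenance" %in% names(df))
      as.character(df$provenance) else NA_character_)
  errs <- character(0)
  dup <- which(duplicated(p$parcel_id))
  if (length(dup)) {
    errs <- c(errs, sprintf("%s %d: duplicate parcel_id '%s'", unit, dup,
                            p$parcel_id[dup]))
  }
  unknown <- which(!(p$ecotype %in% ecotype_labels()))
  if (length(unknown)) {
    errs <- c(errs, sprintf("%s %d: unknown ecotype '%s'", unit, unknown,
                            p$ecotype[unknown]))
  }
  for (i in seq_len(nrow(p))) {
    s <- p$suitability[i]; m <- p$suit_map[[i]]
    if (is.null(m) && (is.na(s) || s < 0 || s > 1)) {
      errs <- c(errs, sprintf("%s %d: suitability %s outside [0, 1]",
                              unit, i, format(s)))
    }
    if (!is.null(m) && any(m < 0 | m > 1)) {
      errs <- c(errs, sprintf("%s %d: mapped suitability outside [0, 1]",
                              unit, i))
    }
    if (is.na(p$area_ha[i]) || p$area_ha[i] <= 0) {
      errs <- c(errs, sprintf("%s %d: area_ha must be > 0", unit, i))
    }
    if (!(p$status[i] %in% c("tradable", "reserve", "retired"))) {
      errs <- c(errs, sprintf("%s %d: unknown status '%s'", unit, i,
                              p$status[i]))
    }
  }
  if (length(errs)) {
    stop("invalid parcel inventory:\n  ", paste(errs, collapse = "\n  "))
  }
  p
}

#' Write a parcel inventory to CSV
#'
#' @param p A [parcels()] inventory.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_parcels <- function(p, path) {
  scols <- suit_col_keys()
  df <- as.data.frame(p[, c("parcel_id", "ecotype", "zone", "area_ha",
                            "suitability", "status", "provenance")])
  if (any(!vapply(p$suit_map, is.null, logical(1)))) {
    for (k in names(scols)) {
      df[[scols[[k]]]] <- vapply(p$suit_map, function(m)
        if (is.null(m)) NA_real_ else unname(m[[k]]), numeric(1))
    }
  }
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

txn_to_list <- function(j, i) {
  list(
    txn_id = j$txn_id[i], kind = j$kind[i], date = format(j$date[i]),
    pwsa_delta = j$pwsa_delta[i],
    offset_ratio = if (is.na(j$offset_ratio[i])) NULL else j$offset_ratio[i],
    maturity_date = if (is.na(j$maturity_date[i])) NULL else
      format(j$maturity_date[i]),
    schedule = if (is.na(j$schedule[i])) NULL else j$schedule[i],
    justification = if (is.na(j$justification[i])) NULL else
      j$justification[i],
    cost_note = if (is.na(j$cost_note[i])) NULL else j$cost_note[i],
    warning_flag = j$warning_flag[i],
    detail = j$detail[[i]])
}

txn_from_list <- function(e) {
  tibble::tibble(
    txn_id = e$txn_id, kind = e$kind, date = as.Date(e$date),
    pwsa_delta = as.numeric(e$pwsa_delta),
    offset_ratio = as.numeric(e$offset_ratio %||% NA_real_),
    maturity_date = as.Date(e$maturity_date %||% NA_character_),
    schedule = as.character(e$schedule %||% NA_character_),
    justification = as.character(e$justification %||% NA_character_),
    cost_note = as.character(e$cost_note %||% NA_character_),
    warning_flag = isTRUE(e$warning_flag),
    detail = list(e$detail))
}

#' Write a transaction journal as JSON lines
#'
#' One transaction per line, in journal order, in a canonical form:
#' write-then-read round-trips to an identical journal (and an identical
#' balance sheet), and rewriting a reloaded journal reproduces the file
#' byte for byte.
#'
#' @param ledger A ledger (or a journal tibble).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_journal <- function(ledger, path) {
  j <- if (inherits(ledger, "service_area_ledger")) ledger$journal else ledger
  lines <- vapply(seq_len(nrow(j)), function(i)
    as.character(jsonlite::toJSON(txn_to_list(j, i), auto_unbox = TRUE,
                                  digits = NA, null = "null")),
    character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a transaction journal from JSON lines
#'
#' Refuses corrupted records and out-of-order entries, naming the offending
#' line.
#'
#' @param path Path to a JSON-lines journal.
#' @return A journal tibble; attach it to a ledger with
#'   [attach_journal()].
#' @export
read_journal <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(empty_journal())
  kinds <- c("deposit", "withdrawal", "trade", "reservation",
             "transfer_out", "transfer_in")
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    e <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                  error = function(err)
                    stop("journal line ", i, ": corrupted record (",
                         conditionMessage(err), ")", call. = FALSE))
    if (is.null(e$kind) || !(e$kind %in% kinds)) {
      stop("journal line ", i, ": unknown transaction kind '",
           e$kind %||% "<missing>", "'")
    }
    if (is.null(e$txn_id) || is.null(e$date)) {
      stop("journal line ", i, ": record lacks txn_id or date")
    }
    rows[[i]] <- txn_from_list(e)
  }
  j <- dplyr::bind_rows(rows)
  ord <- order(j$date, j$txn_id)
  if (!identical(ord, seq_len(nrow(j)))) {
    first_bad <- which(ord != seq_len(nrow(j)))[1]
    stop("journal line ", first_bad,
         ": records out of (date, txn_id) order")
  }
  j
}

#' Attach a reloaded journal to a ledger and replay it
#'
#' @param ledger A ledger whose baseline inventory the journal refers to
#'   (its own journal is replaced).
#' @param journal A journal tibble from [read_journal()].
#' @return The ledger with the journal applied to the baseline inventory.
#' @export
attach_journal <- function(ledger, journal) {
  ledger$journal <- journal
  st <- replay_state(ledger)
  ledger$parcels <- st$parcels
  ledger$accounts <- st$accounts
  ledger
}

parcels_to_records <- function(p) {
  lapply(seq_len(nrow(p)), function(i) parcel_row_as_list(p, i))
}

parcels_from_records <- function(recs) {
  if (!length(recs)) return(parcels())
  do.call(bind_parcels, lapply(recs, function(r) parcels(
    parcel_id = r$parcel_id, ecotype = r$ecotype,
    area_ha = r$area_ha,
    suitability = r$suitability %||% NA_real_,
    suit_map = list(if (is.null(r$suit_map)) NULL else unlist(r$suit_map)),
    status = r$status %||% "tradable", zone = r$zone %||% NA_character_,
    provenance = r$provenance %||% NA_character_,
    deposit_txn = r$deposit_txn %||% NA_character_)))
}

#' Serialize a whole ledger to JSON
#'
#' Stores the configuration (ecotypes, guild weights, maturation, offset
#' ratio, objectives, boundary metadata), the baseline inventory and the
#' journal. Reloading with [read_ledger()] replays the journal from the
#' baseline, so a round trip reproduces validation results and valuation
#' totals exactly.
#'
#' @param ledger A `service_area_ledger`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ledger <- function(ledger, path) {
  gw <- ledger$guild_weights
  obj <- list(
    name = ledger$name,
    boundary_metadata = ledger$boundary_metadata,
    ecotypes = lapply(seq_len(nrow(ledger$ecotypes)), function(i) list(
      name = ledger$ecotypes$name[i], ppi = ledger$ecotypes$ppi[i],
      description = if (is.na(ledger$ecotypes$description[i])) NULL else
        ledger$ecotypes$description[i])),
    guild_weights = if (is.null(gw)) NULL else list(
      rows = rownames(gw), cols = colnames(gw),
      values = unclass(unname(gw))),
    offset_ratio = ledger$offset_ratio,
    maturation = ledger$maturation,
    objectives = if (is.null(ledger$objectives)) NULL else
      lapply(seq_len(nrow(ledger$objectives)), function(i) list(
        column = ledger$objectives$column[i],
        target_ha = ledger$objectives$target_ha[i],
        target_pct = ledger$objectives$target_pct[i])),
    baseline_parcels = parcels_to_records(ledger$baseline_parcels),
    journal = lapply(seq_len(nrow(ledger$journal)), function(i)
      txn_to_list(ledger$journal, i)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Load a ledger serialized by [write_ledger()]
#'
#' @param path Path to the JSON file.
#' @return A `service_area_ledger` with the journal replayed from the
#'   baseline inventory.
#' @export
read_ledger <- function(path) {
  o <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  eco <- ecotype_table(
    name = vapply(o$ecotypes, `[[`, character(1), "name"),
    ppi = vapply(o$ecotypes, `[[`, numeric(1), "ppi"),
    description = vapply(o$ecotypes, function(e)
      e$description %||% NA_character_, character(1)))
  gw <- NULL
  if (!is.null(o$guild_weights)) {
    vals <- do.call(rbind, lapply(o$guild_weights$values, unlist))
    dimnames(vals) <- list(unlist(o$guild_weights$rows),
                           unlist(o$guild_weights$cols))
    gw <- guild_weight_table(vals)
  }
  objv <- NULL
  if (!is.null(o$objectives) && length(o$objectives)) {
    objv <- objective_set(
      column = vapply(o$objectives, `[[`, character(1), "column"),
      target_ha = vapply(o$objectives, function(x)
        as.numeric(x$target_ha %||% NA_real_), numeric(1)),
      target_pct = vapply(o$objectives, function(x)
        as.numeric(x$target_pct %||% NA_real_), numeric(1)))
  }
  ledger <- service_area_ledger(
    name = o$name, ecotypes = eco, guild_weights = gw,
    parcels = parcels_from_records(o$baseline_parcels),
    objectives = objv, boundary_metadata = o$boundary_metadata,
    offset_ratio = o$offset_ratio %||% 1,
    maturation = o$maturation %||% list(schedule = "step", lag_days = 0))
  journal <- if (length(o$journal)) {
    dplyr::bind_rows(lapply(o$journal, txn_from_list))
  } else {
    empty_journal()
  }
  attach_journal(ledger, journal)
}

#' Build a ledger skeleton from a JSON configuration
#'
#' The configuration holds the service-area defaults: ecotype/PPI table,
#' guild weights, maturation, offset ratio, objectives and boundary
#' metadata. Omitted sections fall back to the packaged defaults.
#'
#' @param path Path to a JSON config.
#' @return A `service_area_ledger` with an empty inventory.
#' @export
read_config <- function(path) {
  o <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  eco <- if (is.null(o$ecotypes)) default_ecotypes() else ecotype_table(
    name = vapply(o$ecotypes, `[[`, character(1), "name"),
    ppi = vapply(o$ecotypes, `[[`, numeric(1), "ppi"),
    description = vapply(o$ecotypes, function(e)
      e$description %||% NA_character_, character(1)))
  gw <- if (is.null(o$guild_weights)) default_guild_weights() else {
    vals <- do.call(rbind, lapply(o$guild_weights$values, unlist))
    dimnames(vals) <- list(unlist(o$guild_weights$rows),
                           unlist(o$guild_weights$cols))
    guild_weight_table(vals)
  }
  objv <- NULL
  if (!is.null(o$objectives) && length(o$objectives)) {
    objv <- objective_set(
      column = vapply(o$objectives, `[[`, character(1), "column"),
      target_ha = vapply(o$objectives, function(x)
        as.numeric(x$target_ha %||% NA_real_), numeric(1)),
      target_pct = vapply(o$objectives, function(x)
        as.numeric(x$target_pct %||% NA_real_), numeric(1)))
  }
  service_area_ledger(
    name = o$name %||% "service-area", ecotypes = eco, guild_weights = gw,
    objectives = objv, boundary_metadata = o$boundary_metadata,
    offset_ratio = o$offset_ratio %||% 1,
    maturation = o$maturation %||% list(schedule = "step", lag_days = 0))
}
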
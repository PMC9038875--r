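#' Build a parcel inventory
#'
#' A parcel is an area of one ecotype with suitability information and a
#' trading status. Suitability is either a scalar in [0, 1] or a
#' guild-resolved map over the nine (thermal guild, life stage) keys; the two
#' forms are both first class and are collapsed by [effective_suitability()].
#'
#' @param parcel_id Unique character ids.
#' @param ecotype Ecotype label per parcel (see [ecotype_labels()]).
#' @param area_ha Parcel areas in hectares, strictly positive.
#' @param suitability Scalar suitabilities in [0, 1]; `NA` for parcels that
#'   carry a guild-resolved map instead.
#' @param suit_map Optional list of named numeric vectors (names are
#'   `<guild>.<stage>` keys) for guild-resolved parcels; `NULL` entries for
#'   scalar parcels.
#' @param status Trading status: `tradable`, `reserve` or `retired`.
#' @param zone Optional reporting zone (e.g. `mainland` / `islands` for
#'   terrestrial land); used only to label balance-sheet columns.
#' @param provenance Free text (natural / restored / created).
#' @param deposit_txn Internal: id of the deposit transaction that created a
#'   bank parcel, `NA` otherwise.
#' @return A tibble of class `hb_parcels`.
#' @export
parcels <- function(parcel_id = character(), ecotype = character(),
                    area_ha = numeric(), suitability = numeric(),
                    suit_map = NULL, status = "tradable", zone = NA_character_,
                    provenance = NA_character_, deposit_txn = NA_character_) {
  n <- length(parcel_id)
  if (is.null(suit_map)) suit_map <- vector("list", n)
  out <- tibble::tibble(
    parcel_id = as.character(parcel_id),
    ecotype = as.character(ecotype),
    zone = rep_len(as.character(zone), n),
    area_ha = as.numeric(area_ha),
    suitability = rep_len(as.numeric(suitability), n),
    suit_map = suit_map,
    status = rep_len(as.character(status), n),
    provenance = rep_len(as.character(provenance), n),
    deposit_txn = rep_len(as.character(deposit_txn), n)
  )
  class(out) <- c("hb_parcels", class(out))
  out
}

as_parcels <- function(df) {
  df <- tibble::as_tibble(df)
  parcels(
    parcel_id = df$parcel_id, ecotype = df$ecotype, area_ha = df$area_ha,
    suitability = if ("suitability" %in% names(df)) df$suitability else NA_real_,
    suit_map = if ("suit_map" %in% names(df)) df$suit_map else NULL,
    status = if ("status" %in% names(df)) df$status else "tradable",
    zone = if ("zone" %in% names(df)) df$zone else NA_character_,
    provenance = if ("provenance" %in% names(df)) df$provenance else NA_character_,
    deposit_txn = if ("deposit_txn" %in% names(df)) df$deposit_txn else NA_character_
  )
}

# rbind that survives the list-column
bind_parcels <- function(...) {
  out <- dplyr::bind_rows(...)
  class(out) <- unique(c("hb_parcels", class(out)))
  out
}

validate_parcels <- function(p, ecotype_names) {
  bad <- character(0)
  dup <- unique(p$parcel_id[duplicated(p$parcel_id)])
  if (length(dup)) {
    bad <- c(bad, sprintf("parcel '%s': duplicate parcel_id", dup))
  }
  unknown <- !(p$ecotype %in% ecotype_names)
  if (any(unknown)) {
    bad <- c(bad, sprintf("parcel '%s': unknown ecotype '%s'",
                          p$parcel_id[unknown], p$ecotype[unknown]))
  }
  nonpos <- !is.na(p$area_ha) & p$area_ha <= 0
  if (any(nonpos | is.na(p$area_ha))) {
    ids <- p$parcel_id[nonpos | is.na(p$area_ha)]
    bad <- c(bad, sprintf("parcel '%s': area_ha must be > 0", ids))
  }
  for (i in seq_len(nrow(p))) {
    s <- p$suitability[i]
    m <- p$suit_map[[i]]
    if (is.null(m)) {
      if (is.na(s) || s < 0 || s > 1) {
        bad <- c(bad, sprintf("parcel '%s': suitability %s outside [0, 1]",
                              p$parcel_id[i], format(s)))
      }
    } else {
      if (any(m < 0 | m > 1)) {
        bad <- c(bad, sprintf("parcel '%s': mapped suitability outside [0, 1]",
                              p$parcel_id[i]))
      }
    }
  }
  badstat <- !(p$status %in% c("tradable", "reserve", "retired"))
  if (any(badstat)) {
    bad <- c(bad, sprintf("parcel '%s': unknown status '%s'",
                          p$parcel_id[badstat], p$status[badstat]))
  }
  bad
}

# non-retired rows only: a retired parcel never re-enters valuation totals
active_parcels <- function(p) p[p$status != "retired", , drop = FALSE]
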
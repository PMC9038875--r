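---
title: "Methods: productivity-weighted habitat accounting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: productivity-weighted habitat accounting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(habbank)
```

## The accounting model

`habbank` tracks the habitat supply of a bounded aquatic *service area* in a
single currency, **productivity-weighted suitable area (PWSA)**, and records
every change to that supply in an append-only transaction journal.

Valuation composes three layers:

1. **Parcel suitability** `S` in [0, 1]: how good a parcel is relative to
   the best habitat of its ecotype. It is either a scalar or a map over the
   nine (thermal guild, life stage) combinations — cold/cool/warm crossed
   with spawning/nursery/juvenile+adult.
2. **Weighted suitable area** `WSA = sum(A_p * S_p)` per ecotype, in
   suitability-weighted hectares: the within-ecotype quality measure.
3. **PWSA = PPI * WSA**, where the **potential productivity index (PPI)**
   is a dimensionless per-ecotype scalar expressing relative maximum
   ongoing productivity — the between-ecotype exchange rate. The packaged
   defaults are rivermouth 1.5, wetland 2.0, embayment 1.0, open coast 0.5,
   offshore 0.25 and terrestrial 0.

One PWSA unit therefore equals one hectare at suitability 1 in a PPI-1
ecotype. Terrestrial land is modelled as a sixth ecotype with PPI 0 rather
than excluded, so converting land to water (or infilling water) is an
ordinary ecotype change and **total hectares are conserved by every
transaction**. This choice has a pleasant consequence in the packaged
worked example: the mainland loses 1 ha to a wetland deposit and regains
1 ha from an embayment infill, so its updated area is unchanged and the
grand total stays at 15,670 ha.

### Guild-weighted suitability

When a parcel carries guild-resolved suitabilities, they are collapsed with
the ecotype's percent weight column:

`S_eff = sum over (g, s) of w[g, s, e] / 100 * S[g, s]`.

The combination formula is a design choice of this package (the framework
prescribes guild weighting but not its algebra). A convex combination was
chosen because each weight column sums to 100, so the result stays in
[0, 1] and reduces to the identity for uniform maps — e.g. all nine values
at 0.5 give exactly 0.5, and a wetland parcel suitable only for the three
warm-water stages scores (19 + 22 + 19)/100 = 0.60 under the default
weights.

### Quality classes

High / Med / Low classes carry representative suitabilities 0.75 / 0.50 /
0.25. For classifying arbitrary suitabilities the band edges are the
midpoints 0.375 and 0.625, half-open on the upper edge (0.625 is High).
Classes are a reporting convenience only; full-precision suitabilities
drive all accounting, and rounding (areas to 1 decimal, PWSA to 2) happens
only at rendering.

## Transactions

* **Deposit** — habitat creation or enhancement. The PWSA delta is
  post-minus-pre over the affected footprint and must be positive; the
  converted source footprint is retired (terrestrial sources count zero
  aquatic value beforehand). A *deposit account* opens with that delta.
* **Maturation** — a deposit's value is held until the habitat is
  ecologically functional. Two schedules are provided because the framework
  describes the concept, not a functional form: `step` (default; no value
  until the maturity date — the cheque must clear) and `linear` (value
  ramps from the construction date to maturity). `available = full * m(t)
  - committed`.
* **Withdrawal** — an unavoidable development impact; delta is
  post-minus-pre and must not be positive. Reserve parcels cannot be
  impacted. Withdrawals may precede their offsetting trade: in practice
  deposits rarely all come first in a working city, so an uncovered loss is
  representable and simply leaves the balance sheet lower until a trade
  covers it.
* **Offset solver** — the deposit area needed to cover a loss is the
  inverse of valuation: `area = r * loss / (S_eff * PPI)`, with offset
  ratio `r >= 1` (default 1) available for time-lag or uncertainty policy.
  Valuing the solved area reproduces `r * loss` to 1e-9 by construction.
* **Trade** — debits matured deposit accounts FIFO by maturity date (ties
  by transaction id; the framework is silent, FIFO matches the banking
  metaphor), and moves the used portions of the deposit parcels into the
  natural capital reserves. Partial debits split the parcel into a reserved
  used-portion and a tradable remainder at unchanged suitability. Each
  withdrawal can be offset by exactly one trade.
* **Reserves** — a one-way street: reservations and traded portions only
  ever add to the reserve set.
* **Transfers** — inter-area movements of *banked* value (not physical
  habitat): the source bank is debited exactly like a trade and the target
  gains an immediately-available external credit. Both entries always carry
  a warning flag and require a non-empty justification, reflecting the
  precautionary stance on inter-bank transfers.

### Journal and replay

Every transaction stores the primitive operations it performed (shrink /
add / status / account open / account debit). `replay()` re-applies exactly
those operations from the baseline inventory, so recording and replaying
share one code path: a reloaded journal reproduces the live valuation
bit-for-bit, and balance sheets at any date are replays up to that date.
The "current" supply row of a sheet is defined as replay-to-date.

## The packaged worked example

`make_toronto_fixture()` encodes the worked nearshore example: ecotype
areas 30/160/830/14,000/440 ha plus 130 + 80 ha of terrestrial buffer,
class fractions High 60/80/50/65/50 %, Med 10/15/40/25/30 %, Low
30/5/10/10/20 %, the default PPI table and guild weights, notional area
objectives, and a three-transaction journal (1-ha land-to-wetland deposit,
1-ha embayment infill, equivalency trade at r = 1). The inventory uses one
parcel per (ecotype, quality class) — the coarsest inventory that realises
the published class block exactly.

Two inventory variants exist because the published material itself uses
two conventions: the quality-class variant reproduces the class totals
(High 9881 / Med 3991 / Low 1588 ha) and the 1.50/−0.50/⅓-ha trade, while
the unit-suitability variant (every aquatic hectare at S = 1) reproduces
the supply balance sheet: baseline 8305 PWSA, updated 8306, bank remainder
1.0 PWSA over 0.5 ha.

Two published cells are knowingly not reproduced, because they are
internally inconsistent with the framework's own arithmetic:

* the offshore baseline PWSA printed in the source sheet equals
  0.5 x WSA rather than its stated PPI 0.25 x WSA; the engine always
  computes `pwsa = ppi * wsa`, so the printed grand total that depends on
  that cell is not a verification target;
* the narrative calls the traded portion "0.33 PWSA units" where the trade
  table shows 0.33 *ha* carrying 0.50 PWSA; the engine treats 0.33 as area
  and 0.50 as PWSA — the only arithmetically consistent reading.

Likewise the notional objective hectares do not sum to the printed total
(15,608 vs 15,670); they are notional inputs and are reported as given,
never "corrected".

## The synthetic generator

`generate_service_area()` emulates the structure of a real inventory —
ecotype area totals split over parcels, suitabilities from either class
fractions or a Beta distribution, an optional pre-reserved fraction, and
simulated deposit/withdrawal/trade cycles. A single integer seed drives one
explicit pseudo-random stream (the global RNG state is saved and
restored), so generation is reproducible. Parcel areas are exponential
spacings normalised to the requested totals, giving realistic skewed parcel
sizes while matching totals exactly.

What the generator does *not* emulate: spatial arrangement and adjacency
(no geometry is generated or used), temporal clustering of development
pressure, correlated suitabilities between neighbouring parcels, and
measurement error in suitability assessment. A green test therefore
establishes the accounting arithmetic and rule enforcement, not the
ecological realism of any particular suitability assignment.

## Numerical choices

* All arithmetic is double precision; display rounding never feeds back.
* Footprint and balance comparisons use a 1e-9 tolerance; a shrink that
  exhausts a parcel within that tolerance retires it (the row keeps its
  historical area for the record but leaves all valuation totals).
* Offset ratios below 1 are rejected rather than silently clamped, as are
  suitabilities outside [0, 1] and non-positive areas — no unit
  auto-detection anywhere.
* Dates are whole days with `(date, txn_id)` as the total journal order;
  the framework gives no finer temporal resolution.

## Known limitations

* Suitabilities are inputs: the package does not estimate them from
  habitat variables (depth, substrate, vegetation), and produces relative
  PWSA units, not absolute fish production.
* Financial costing is carried as free text only; nothing is computed.
* GeoJSON geometry is stored provenance, never a source of area — keeping
  the engine free of projection/CRS decisions.
* One trade fully offsets one withdrawal; partial or pooled offsetting of
  a single withdrawal across multiple trades is not modelled.
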
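# habbank

An ecological-accounting ledger for **aquatic habitat banking**. It is
written for habitat managers, offset planners and regulators who need to
track losses and gains of fish habitat across a bounded planning ("service")
area in one common currency, and to prove no-net-loss arithmetic from an
auditable transaction journal.

## The model

Habitat parcels are valued in **productivity-weighted suitable area
(PWSA)**:

* per parcel, a suitability *S* in [0, 1] — scalar, or a map over thermal
  guild x life stage collapsed with ecotype-specific percent weights,
  `S_eff = Σ w_{g,s,e}/100 · S_{g,s}`;
* per ecotype, weighted suitable area `WSA_e = Σ A_p · S_eff(p)`
  (suitability-weighted hectares);
* `PWSA_e = PPI_e · WSA_e`, where the potential productivity index (PPI) is
  the between-ecotype exchange rate (defaults: rivermouth 1.5, wetland 2.0,
  embayment 1.0, open coast 0.5, offshore 0.25, terrestrial 0).

On top of the valuation sits a double-entry ledger: **deposits** (habitat
creation, with a maturation hold until "the cheque clears"),
**withdrawals** (development impacts), **equivalency trades** (an inverse
solver returns the deposit area `r · loss / (S_eff · PPI)` needed at offset
ratio `r`; traded portions move into natural-capital **reserves**),
**reservations**, and flagged inter-area **transfers**. The journal is
append-only and replayable: balance sheets at any date are recomputed from
the baseline inventory plus the journal.

## Worked example

The packaged fixture is a Toronto-nearshore planning area (15,670 ha over
five aquatic ecotypes plus terrestrial buffer) with a three-transaction
journal: a 1-ha land-to-wetland deposit, a 1-ha embayment infill, and the
trade between them.

```r
library(habbank)
ledger <- make_toronto_fixture()          # quality-class inventory
last_transaction(ledger)$kind             # "trade"

base <- make_toronto_fixture(include_journal = FALSE)
attr(quality_distribution(base$parcels, base$guild_weights), "class_totals")
#> High  Med  Low
#> 9881 3991 1588

unit <- make_toronto_fixture(unit_suitability = TRUE)
balance_sheet(unit)
```

```
Habitat supply balance sheet (as of 2025-07-01)
PWSA (productivity-weighted suitable area, 2 dp):
           mainland islands rivermouth wetland embayment open_coast offshore   total
baseline          0       0         45     320       830       7000      110 8305.00
deposit           0       0          0       2         0          0        0    2.00
withdrawal        0       0          0       0        -1          0        0   -1.00
trade             0       0          0       0         0          0        0    0.00
bank              0       0          0       1         0          0        0    1.00
updated           0       0         45     322       829       7000      110 8306.00
Area (ha, 1 dp):
           mainland islands rivermouth wetland embayment open_coast offshore   total
baseline        130      80         30     160       830      14000      440 15670.0
deposit          -1       0          0       1         0          0        0     0.0
withdrawal        1       0          0       0        -1          0        0     0.0
trade             0       0          0       0         0          0        0     0.0
bank              0       0          0     0.5         0          0        0     0.5
updated         130      80         30     161       829      14000      440 15670.0
```

Reading the sheet: the deposit converted 1 ha of mainland into wetland
(+2.0 PWSA at unit suitability), the withdrawal infilled 1 ha of embayment
(−1.0 PWSA, returning 1 ha of land to the mainland), and the trade debited
1.0 PWSA (0.5 ha) of the matured deposit into the reserves, netting to
zero. Total supply rises from 8305 to 8306 PWSA, total area is conserved at
15,670 ha, and 1.0 PWSA (0.5 ha) of deposit remains banked for a future
trade.

The same engine drives the offset arithmetic directly:

```r
solve_offset(0.5, suitability = 0.75, ppi = 2.0, offset_ratio = 1)
#> [1] 0.3333333   # a third of the 1-ha wetland deposit offsets the loss
```

## Command line

A thin CLI wraps the same functions (`init`, `value`, `deposit`,
`withdraw`, `trade`, `transfer`, `reserve`, `report`, `demo`):

```sh
Rscript inst/cli/habbank demo --unit-suitability
Rscript inst/cli/habbank value --parcels inventory.csv
```

Domain errors (hold rule, reserve rule, insufficient balance) exit 1; usage
errors exit 2.

## Acceptance script

`scripts/acceptance.R` rebuilds the worked single-trade scenario from
scratch with the installed package — records the deposit, the withdrawal
and the trade — and writes the resulting deposit gain, withdrawal loss and
solved offset-area percentage to JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
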
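# groundtruthr

Accuracy and cost analysis of **modified ground-truthing** for validating
commercial food-store listings in town and rural study areas.

Commercial business listings (the usual data source for food-environment
exposure measures) are error-prone outside cities: phantom records, missing
stores, and listed establishments that are not food stores at all. Full
ground-truthing — driving every street and enumerating every outlet — fixes
this but is costly. `groundtruthr` simulates and scores the modified
alternative: build *central commercial clusters* (the union of 1/8-mile /
200 m buffers around any group of ≥ 2 listed stores, linked when buffers
touch), canvass only the cluster interiors, and handle out-of-cluster listed
records by a bracketing assumption (all open, or all closed).

For a list judged against a ground-truthed census, with TP = listed stores
verified open, FP = listed records not found or ineligible, and FN = open
stores missing from the list:

    PPV = TP / (TP + FP)        sensitivity = TP / (TP + FN)

aggregated across sites by macro-averaging (mean of per-site values). The
assume-closed scenario has FP = 0 structurally, so its PPV is 1 whenever any
store is verified. Costs follow miles: canvass miles = road miles × a
back-tracking factor (default 1.27), transit miles = trips × round-trip
miles, dollars = miles × $0.565.

The package provides:

* `synth_config()` / `generate_site()` — synthetic foodscapes: gridded road
  networks, clustered-plus-isolated store censuses, and error-laden listings
  (omissions, phantoms, ineligible records, coordinate jitter, name noise);
* `match_records()` — exact/close/lenient name-tier matching with a distance
  gate, or id-based oracle matching on synthetic data;
* `link_components()` / `build_zones()` — cluster zones with exact
  disc-union geometry (area, containment, road clipping);
* `simulate_modified()` / `confusion_vs_census()` — the two canvass
  scenarios scored against the census;
* `ppv()`, `sensitivity()`, `macro_average()`, `cost_report()` and rendered
  accuracy/cost tables;
* `make_reference_fixture()` — a deterministic three-site example
  (synthetic, reconstructed from published summary counts) that the full
  pipeline reproduces cell for cell;
* `run_pipeline()` plus a thin CLI (`inst/cli/foodscape.R`) with
  `run` / `zones` / `evaluate` / `cost` subcommands.

## Worked example

```r
library(groundtruthr)

b <- make_reference_fixture("B")
b
#> <site_bundle> B: 72 census stores (72 eligible), 74 listing records

res <- evaluate_site(b)   # match -> zones -> both scenarios -> confusion
res$zones
#> <zone_set> 1 zone(s), buffer radius 200.0 m
#>   zone 1: 62 members, area 0.624 km^2
res$confusions
#> # A tibble: 3 × 5
#>   site  list             tp    fp    fn
#>   <chr> <chr>         <int> <int> <int>
#> 1 B     commercial       48    26    24
#> 2 B     assume_open      69     9     3
#> 3 B     assume_closed    66     0     6
```

The raw commercial list finds 48 of site B's 72 open stores (sensitivity
0.67) and carries 26 bad records (PPV 0.65). Canvassing only the single
62-store cluster zone and assuming everything outside it closed verifies 66
stores with no false positives: PPV 1.00, sensitivity 0.92.

```r
ref <- reference_cost_inputs()
cost_report(ref$traditional, ref$modified)$savings
#> # A tibble: 7 × 5
#>   metric        traditional modified amount   pct
#>   <chr>               <dbl>    <dbl>  <dbl> <dbl>
#> 1 road_miles           564      67     497   88.1
#> 2 driven_miles         718      85.1   633.  88.1
#> 3 to_from_miles        792     392     400   50.5
#> 4 total_miles         1510     477.   1033.  68.4
#> 5 trips                  6       3       3   50  
#> 6 mileage_cost         406.     48.1   358.  88.1
#> 7 total_cost           853.    270.    584.  68.4
```

Driving all 564 network miles took 1510 total miles and $853; restricting
the canvass to cluster zones cuts ground-truthing road miles and mileage
cost by 88 % and trips by half.

A full run (site tables, zone GeoJSON, classifications, validated lists,
rendered accuracy and cost tables, manifest):

```r
run_pipeline(list(sites = "reference"), "out/")
# or, from a shell:
#   Rscript inst/cli/foodscape.R run --config config.yaml --out out/
```

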
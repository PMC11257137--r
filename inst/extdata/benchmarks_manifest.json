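{
  "source": "Published benchmark-comparison tables for the 2020 NHIS adult population and a large US volunteer research cohort (N = 100,391 complete cases; data May 2017 - January 2022), transcribed at the printed 2-decimal precision.",
  "files": {
    "table2a_demographics.csv": {
      "description": "Demographic profile table: 11 categorical variables, 43 category rows.",
      "columns": {
        "n_sample": "cohort sample size per category",
        "benchmark_pct": "2020 NHIS, % (N = 35,399)",
        "unweighted_pct": "Unweighted prevalence estimate (%)",
        "unweighted_ci_lo": "Unweighted 95% CI lower bound",
        "unweighted_ci_hi": "Unweighted 95% CI upper bound",
        "diff_unweighted_pct": "Absolute percentage difference (unweighted vs NHIS)",
        "weighted_pct": "Weighted (raked) prevalence estimate (%)",
        "weighted_ci_lo": "Weighted 95% CI lower bound",
        "weighted_ci_hi": "Weighted 95% CI upper bound",
        "diff_weighted_pct": "Absolute percentage difference (weighted vs NHIS)"
      },
      "raked_variables_footnote": ["age", "sex", "race_ethnicity", "region", "income", "home_ownership"]
    },
    "table2b_outcomes.csv": {
      "description": "Prevalence of 6 binary health / health-behavior outcomes; same column layout. Printed summary rows: unweighted MPD 6.25, weighted MPD 5.07, absolute change 1.18, relative change 18.89.",
      "columns": "identical to table2a_demographics.csv"
    }
  }
}
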
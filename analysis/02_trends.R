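#!/usr/bin/env Rscript

# Step 2: publication growth. Reads the corpus export, applies the
# five-per-year inclusion threshold, fits exponential growth on the
# log scale, and reports the doubling time.

suppressMessages(library(beemine))
library(readr)
library(tibble)

corpus <- read_publications("results/data/corpus.csv")
corpus <- filter_years_by_min_count(corpus, 5)
counts <- annual_counts(corpus)
fit <- fit_exponential(counts)

dir.create("results/trends", recursive = TRUE, showWarnings = FALSE)
write_tsv(
  tibble(year = as.integer(names(counts)), count = as.integer(counts)),
  "results/trends/annual_counts.tsv"
)
jsonlite::write_json(
  list(a = fit$a, b = fit$b, r_squared = fit$r_squared, n = fit$n,
       doubling_time = fit$doubling_time),
  "results/trends/growth_fit.json", auto_unbox = TRUE, digits = NA
)

print(fit)
cat(sprintf(
  "publications double every %.2f years (R^2 = %.3f over %d years)\n",
  fit$doubling_time, fit$r_squared, fit$n
))

# prevalence series for a few planted keywords across the regime change
norm <- normalize_corpus(corpus, read_synonym_map("results/data/synonyms.tsv"))
for (kw in c("varroa", "forag", "genom")) {
  series <- keyword_proportion_series(norm, kw)
  write_tsv(
    tibble(year = as.integer(names(series)), proportion = as.numeric(series)),
    sprintf("results/trends/prevalence_%s.tsv", kw)
  )
}
cat("keyword prevalence series written to results/trends/\n")
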
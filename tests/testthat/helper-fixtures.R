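# A hand-built stripe with known geometry, used wherever classification
# logic is tested independently of the simulation.
toy_stripe <- function() {
  structure(data.frame(x = c(0.01, 0.1, 0.3, 0.6),
                       y_lower = c(0.45, 0.55, 0.70, 0.85),
                       y_mid   = c(0.50, 0.60, 0.75, 0.90),
                       y_upper = c(0.55, 0.65, 0.80, 0.95)),
            class = c("transition_stripe", "data.frame"))
}

toy_census <- function() {
  data.frame(
    territory = c("HighBlack", "LowBlack", "MidStripe", "NoBlacks"),
    n_white = c(100, 7000, 400, 50),
    n_free_colored = c(50, 1500, 60, 0),
    n_slave = c(850, 1500, 540, 0),
    creole_observed = c(TRUE, FALSE, TRUE, NA))
}

write_census_file <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE)
  path
}

# convert repertoire masks of one sampled M+B configuration to the chain's
# state key (counts over the 7 repertoire types, M block then B block)
masks_to_key <- function(masks_m, masks_b) {
  tm <- c(1L, 2L, 4L, 3L, 5L, 6L, 7L)
  paste(c(tabulate(match(masks_m, tm), 7), tabulate(match(masks_b, tm), 7)),
        collapse = ",")
}
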
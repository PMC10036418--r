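# Published steady-state simulation tables, encoded as printed strings
# so each cell carries its own rounding tolerance (one unit of the last
# printed digit). Cells that cannot be recovered unambiguously from the
# published table (garbled in row 9) or that are inconsistent with the
# row's own printed parameter overrides (rows 6 and 16; see the matching
# identity assertions in test-scenarios.R) are NA.

.cell_tol <- function(s) {
  if (is.na(s)) return(NA_real_)
  if (grepl("\\.", s)) 10^(-nchar(sub(".*\\.", "", s))) else 1
}

.parse_table <- function(rows) {
  vals <- lapply(rows, function(r) suppressWarnings(as.numeric(r)))
  tol <- lapply(rows, function(r) vapply(r, .cell_tol, numeric(1)))
  list(values = do.call(rbind, vals), tol = do.call(rbind, tol))
}

.tab_cols <- c("GL0", "AL0", "LF0", "GL", "AL", "LF", "LM", "PL", "PF",
               "Kp_brain")

# propranolol simulations 1-10
propranolol_table <- .parse_table(list(
  c("61.7", "28.2", "10.2", "23.6", "55.8", "20.6", "20.6", "959",  "4040", "9.8"),
  c("61.7", "28.2", "10.2", "61.7", "28.2", "10.2", "10.2", "526",  "4473", "5.4"),
  c("87.4", "8.5",  "4.1",  "55.7", "29.6", "14.7", "14.7", "724",  "4276", "7.4"),
  c("61.7", "28.2", "10.2", "22.2", "56.8", "21.0", "21.0", "973",  "4026", "9.9"),
  c("61.7", "28.2", "10.2", "33.6", "48.6", "17.9", "17.9", "854",  "4145", "8.7"),
  c("61.7", "28.2", "10.2", "61.7", "28.2", "10.2", NA,     NA,     NA,     "5.4"),
  c("61.7", "28.2", "10.2", "23.6", "55.8", "20.6", "2.1",  "116",  "4883", "1.2"),
  c("61.7", "28.2", "10.2", "20.2", "46.5", "17.1", "2.3",  "130",  "4869", "1.3"),
  c("61.7", "28.2", "10.2", "7.61", "19.2", "6.96", NA,     NA,     "4946", "0.55"),
  c("61.7", "28.2", "10.2", "21.9", "51.2", "18.8", "1.2",  "66",   "4934", "0.67")))

# imipramine simulations 11-20
imipramine_table <- .parse_table(list(
  c("45.3", "51.9", "2.73", "11.3", "39.5", "49.2", "50.2", "1880", "3120", "19.3"),
  c("45.3", "51.9", "2.73", "45.3", "51.9", "2.73", "2.78", "162",  "4838", "1.6"),
  c("79.2", "19.4", "1.36", "33.1", "25.1", "41.9", "42.7", "1695", "3305", "17.4"),
  c("45.3", "51.9", "2.73", "11.0", "39.6", "49.4", "50.3", "1884", "3116", "19.3"),
  c("45.3", "51.9", "2.73", "14.1", "38.3", "47.6", "48.6", "1843", "3157", "18.9"),
  c("45.3", "51.9", "2.73", "45.3", "51.9", "2.73", NA,     "161",  "4839", "1.6"),
  c("45.3", "51.9", "2.73", "11.3", "39.5", "49.2", "5.02", "284",  "4716", "2.9"),
  c("45.3", "51.9", "2.73", "6.13", "20.8", "25.6", "6.78", "376",  "4624", "3.8"),
  c("45.3", "51.9", "2.73", "1.13", "3.94", "4.86", "1.29", "76",   "4924", "0.77"),
  c("45.3", "51.9", "2.73", "8.97", "31.1", "38.6", "3.06", "177",  "4823", "1.8")))

expect_table_match <- function(computed, expected) {
  for (i in seq_len(nrow(expected$values))) {
    for (j in seq_along(.tab_cols)) {
      exp_v <- expected$values[i, j]
      if (is.na(exp_v)) next
      expect_lt(abs(computed[i, .tab_cols[j]] - exp_v),
                expected$tol[i, j] + 1e-9,
                label = sprintf("row %d, %s: |%.5g - %.5g|", i,
                                .tab_cols[j], computed[i, .tab_cols[j]],
                                exp_v))
    }
  }
}
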
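# Builds inst/extdata/bladder.csv from the Veterans Administration bladder
# tumour study as shipped in the survival package (bladder1).
#
# Restriction: thiotepa + placebo arms; the single patient with zero
# follow-up (id 1) is dropped, leaving 85 patients (38 thiotepa,
# 47 placebo). All tumour recurrences are retained (132 in total); deaths
# and end of study are treated as censoring for recurrence. Output is the
# package's canonical counting-process dialect with covariates `number`
# (initial tumour count) and `size` (largest initial tumour, cm).
#
# Run from the package root: Rscript data-raw/make-bladder-fixture.R

library(survival)

b <- subset(bladder1, treatment %in% c("placebo", "thiotepa"))
b <- subset(b, ave(stop, id, FUN = max) > 0)  # drop zero follow-up

rows <- do.call(rbind, lapply(split(b, b$id), function(d) {
  d <- d[order(d$stop), ]
  rec <- d$stop[d$status == 1]
  fu <- max(d$stop)
  starts <- c(0, rec)
  stops <- c(rec, fu)
  status <- c(rep(1L, length(rec)), 0L)
  # no trailing censored row when the last recurrence ends follow-up
  m <- length(stops)
  if (stops[m] <= starts[m]) {
    starts <- starts[-m]; stops <- stops[-m]; status <- status[-m]
  }
  data.frame(id = d$id[1], k = seq_along(stops), start = starts,
             stop = stops, status = status,
             treatment = as.integer(d$treatment[1] == "thiotepa"),
             number = d$number[1], size = d$size[1])
}))
rownames(rows) <- NULL

stopifnot(length(unique(rows$id)) == 85,
          sum(rows$status) == 132,
          sum(rows$treatment[!duplicated(rows$id)]) == 38)

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
write.csv(rows, "inst/extdata/bladder.csv", row.names = FALSE, quote = FALSE)
cat("wrote", nrow(rows), "rows\n")
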
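#!/usr/bin/env Rscript
# Sliding-window entropy curves (10-s windows, 90% overlap) for the ten
# benchmark signals under one representative configuration per estimator
# family, plus the curve-shape statistics that summarise how each signal
# structure drives entropy: monotone trends for the chirps and the MIX
# process, saturation for white noise, a concave interior maximum for the
# AR(1) sweep, and step contrasts at the logistic/Lorenz regime change.

suppressMessages(library(entrobench))

seed <- 20190840
dir.create("results", showWarnings = FALSE)

suite <- benchmark_suite(seed)
configs <- list(cfg_pen(3), cfg_mpen(3), cfg_sen(1, 0.2),
                cfg_qsen(1, 0.6), cfg_fen(1, 1, 0.2))

rows <- list()
shapes <- list()
for (id in names(suite)) {
  for (cfg in configs) {
    cv <- entropy_curve(suite[[id]], cfg)
    rows[[length(rows) + 1L]] <-
      data.frame(signal = id, config = cfg$label, end_time_s = cv$time,
                 value = cv$value, defined = cv$defined)
    ok <- cv$defined
    contrast20 <- tryCatch(transition_contrast(cv, 20), error = function(e) NA)
    shapes[[length(shapes) + 1L]] <- data.frame(
      signal = id, config = cfg$label,
      spearman_time = suppressWarnings(
        cor(cv$time[ok], cv$value[ok], method = "spearman")),
      min_value = min(cv$value[ok]), max_value = max(cv$value[ok]),
      argmax_window = which.max(ifelse(ok, cv$value, -Inf)),
      n_windows = nrow(cv), n_undefined = sum(!ok),
      contrast_t20 = contrast20)
  }
}
curves <- do.call(rbind, rows)
shape_tab <- do.call(rbind, shapes)
curves$value <- round(curves$value, 6)
write.csv(curves, "results/entropy_curves.csv", row.names = FALSE)
write.csv(shape_tab, "results/curve_shapes.csv", row.names = FALSE)

pen <- shape_tab[shape_tab$config == "PEn(n=3)", ]
rownames(pen) <- pen$signal
cat("PEn(n=3) curve shapes over the benchmark suite:\n\n")
print(pen[, c("spearman_time", "min_value", "max_value", "argmax_window",
              "contrast_t20")], digits = 3)
cat(sprintf("
Findings (PEn n = 3 unless noted):
 - chirp / modulated chirp: monotone rise with frequency (Spearman %.2f / %.2f)
 - MIX process: monotone fall as determinism takes over (Spearman %.2f)
 - stepped-power WGN: saturated, all normalized values above %.3f
 - AR(1) sweep: interior maximum at window %d of %d (white noise mid-sweep)
 - logistic map: positive step at t = 20 s (contrast %+.3f; SEn m=1 r=0.2 %+.3f)
 - Lorenz system: positive step at t = 20 s (contrast %+.3f)
",
  pen["chirp", "spearman_time"], pen["chirp_mod", "spearman_time"],
  pen["mix", "spearman_time"], pen["wgn_power", "min_value"],
  pen["ar1_sweep", "argmax_window"], pen["ar1_sweep", "n_windows"],
  pen["logistic", "contrast_t20"],
  shape_tab$contrast_t20[shape_tab$signal == "logistic" &
                           shape_tab$config == "SEn(m=1,r=0.2)"],
  pen["lorenz", "contrast_t20"]))
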
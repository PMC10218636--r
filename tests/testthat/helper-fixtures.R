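# Reference operating point used across tests: the continuous glucose-limited
# steady state of the 1.7 L reactor (printed process-table values).
rs_point <- list(
  D = 0.098,            # 1/h
  X = 5.06,             # g/L dry biomass
  S_res = 5.16,         # residual glucose, mmol_C/L (0.86 mmol/L)
  S_min = 1.68,         # starvation minimum, mmol_C/L (0.28 mmol/L)
  q_glucose = 32.1,     # mmol_C/g/h
  q_max = 71.50,
  K_S = 6.19
)

rs_kinetics <- function(...) uptake_kinetics(q_max = 71.50, K_S = 6.19, ...)

# tiny deterministic count fixture: 4 genes x 4 samples, two conditions
tiny_counts <- function() {
  m <- matrix(c(10, 12, 30, 28,
                100, 90, 210, 190,
                5, 4, 6, 5,
                0, 0, 0, 0), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:4)))
  list(counts = m,
       design = data.frame(sample = paste0("s", 1:4),
                           condition = c("A", "A", "B", "B")))
}
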
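# Independent brute-force oracle for the iterative growth model: re-evaluates
# the effective-LI correction, the cell-number update and the volume-allometry
# inversion day by day, with its own arithmetic (no package functions).
oracle_growth <- function(d0, li0, days, adj = 0.795, slope = 8e-4,
                          coefv = 0.18, expo = 3.05, vg = 132.6) {
  n <- coefv * d0^expo / vg
  d <- d0
  out <- data.frame(day = 0L, diameter = d, cell_count = n)
  for (i in seq_len(days)) {
    li <- adj * max(0, li0 - slope * (d - d0))
    li <- min(1, max(0, li))
    n <- n + n * li
    d <- (n * vg / coefv)^(1 / expo)
    out <- rbind(out, data.frame(day = i, diameter = d, cell_count = n))
  }
  out
}

# numeric inversion of the diameter <-> cell count relation by bisection,
# used as an oracle against the closed form
oracle_diameter_bisect <- function(cell_count, coefv = 0.18, expo = 3.05,
                                   vg = 132.6, lo = 0, hi = 5000) {
  f <- function(d) coefv * d^expo / vg - cell_count
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# printed summary-table values (2 significant figures): mural volume (um^3),
# mural cell count, mean proliferation rate (%), daily cell-number increase
table1_printed <- data.frame(
  diameter_um = seq(100, 450, by = 50),
  mural_volume_um3 = c(2.3e5, 7.8e5, 1.9e6, 3.7e6, 6.5e6, 1.0e7, 1.6e7, 2.2e7),
  cell_count = c(1.7e3, 5.7e3, 1.4e4, 2.7e4, 4.7e4, 7.6e4, 1.1e5, 1.6e5),
  rate_percent = c(49, 45, 41, 37, 33, 29, 25, 21),
  cell_increase = c(8.2e2, 2.6e3, 5.6e3, 1.0e4, 1.6e4, 2.2e4, 2.9e4, 3.4e4)
)
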
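# Shared fixtures, all generated in code.

noiseless_world <- function(cell_size = 0.5) {
  d <- domain_spec(cell_size = cell_size)
  st <- generate_climate(d, scenario_spec("GCM-A", "baseline"),
                         noise_sd = 0, seed = 1)
  lc <- generate_landcover(st, default_rules())
  cells <- apply_anthropogenic(lc, d, list())
  list(domain = d, stack = st, landcover = lc, cells = cells,
       cells_clim = cbind(cells, as.data.frame(st$values)))
}

# Two climate clusters perfectly separated on bio1 at the midpoint of a gap.
separable_cells <- function(n_per = 60, gap = c(20, 24), seed = 1) {
  set.seed(seed)
  cells <- data.frame(cell_id = seq_len(2 * n_per),
                      landcover = rep(c("shrubland", "closed_forest"),
                                      each = n_per))
  for (v in paste0("bio", 1:19)) cells[[v]] <- stats::rnorm(2 * n_per)
  cells$bio1 <- c(stats::runif(n_per, gap[1] - 4, gap[1]),
                  stats::runif(n_per, gap[2], gap[2] + 4))
  cells
}

# A single-leaf training problem on one variable: presence inside a box.
box_train <- function(n = 120, lo = 22, hi = 25, seed = 1) {
  set.seed(seed)
  x <- matrix(stats::runif(n * 2, 18, 29), n, 2,
              dimnames = list(NULL, c("bio1", "bio2")))
  cells <- as.data.frame(x)
  y <- ifelse(x[, "bio1"] > lo & x[, "bio1"] <= hi, 1L, 2L)
  make_train_set(cells, y, 1L, c("bio1", "bio2"))
}
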
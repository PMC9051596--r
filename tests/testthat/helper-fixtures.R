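# Shared fixtures built once per test run (everything is generated in code).

fx <- new.env()

fx_morph1 <- function() {
  if (is.null(fx$m1)) fx$m1 <- table1_morphology(1)
  fx$m1
}

fx_pop_small <- function() {
  # small population for unit tests; acceptance uses the full 50 cells
  if (is.null(fx$pop12))
    fx$pop12 <- build_planar_population(fx_morph1(), 12, 0.5, seed = 421L)
  fx$pop12
}

fx_scheme <- function() {
  if (is.null(fx$scheme)) fx$scheme <- lu177_default_scheme()
  fx$scheme
}

fx_table <- function() {
  if (is.null(fx$tab)) fx$tab <- water_stopping_power()
  fx$tab
}

fx_scenario <- function(...) activity_scenario(...)

# brute-force DSB clustering oracle: full pair graph (opposite strand,
# separation < max_sep) + connected components by BFS — independent of the
# union-find implementation under test
oracle_cluster_sizes <- function(breaks, max_sep_bp = 10) {
  n <- nrow(breaks)
  if (n == 0) return(integer(0))
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && breaks$strand[i] != breaks$strand[j] &&
        abs(breaks$bp_coordinate[i] - breaks$bp_coordinate[j]) < max_sep_bp)
      adj[i, j] <- TRUE
  }
  comp <- rep(0L, n); cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L || !any(adj[s, ])) next
    cid <- cid + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      if (comp[v] != 0L) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  sizes <- tabulate(comp[comp > 0L])
  sort(sizes[sizes >= 2])
}

# random break set generator for property tests
random_breaks <- function(n, span = 200) {
  data.frame(event_id = 1L,
             bp_coordinate = sample.int(span, n, replace = TRUE) - 1,
             strand = sample(0:1, n, replace = TRUE),
             mechanism = "direct", stringsAsFactors = FALSE)
}
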
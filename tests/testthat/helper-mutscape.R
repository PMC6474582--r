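# Shared fixtures and independent oracles for the test suite. Everything
# here is deliberately written without reusing the package's internal
# helpers, so agreement is a two-route check.

# catalog and a fixed collision-free input triple, computed once
CT3 <- logic_tasks(3)
CT2 <- logic_tasks(2)
INS <- survey_inputs(seed = 424242)

# --- brute-force task enumeration oracle ----------------------------------
# lists all 2^(2^k) boolean functions of k inputs as 0/1 row vectors,
# drops constants, functions ignoring an input, and the 1-input identity,
# and counts equivalence classes under input permutation
oracle_task_count <- function(max_inputs) {
  total <- 0L
  for (k in seq_len(max_inputs)) {
    grid <- as.matrix(expand.grid(rep(list(0:1), k))) # rows x inputs
    perms <- if (k == 1) list(1L) else
      if (k == 2) list(1:2, 2:1) else
        list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
             c(3, 1, 2), c(3, 2, 1))
    seen <- character()
    for (code in 0:(2^(2^k) - 1)) {
      f <- (bitwAnd(bitwShiftR(code, 0:(2^k - 1)), 1L))
      if (all(f == 0) || all(f == 1)) next
      # depends on all inputs?
      dep <- vapply(seq_len(k), function(j) {
        any(vapply(seq_len(nrow(grid)), function(r) {
          other <- grid[r, ]
          other[j] <- 1 - other[j]
          r2 <- which(colSums(abs(t(grid) - other)) == 0)
          f[r] != f[r2]
        }, logical(1)))
      }, logical(1))
      if (!all(dep)) next
      if (k == 1 && all(f == grid[, 1])) next # echo
      keys <- vapply(perms, function(p) {
        g2 <- grid[, p, drop = FALSE]
        idx <- apply(g2, 1, function(x) sum(x * 2^(seq_len(k) - 1))) + 1
        paste0(f[order(idx)], collapse = "")
      }, character(1))
      key <- min(keys)
      if (!key %in% seen) seen <- c(seen, key)
    }
    total <- total + length(seen)
  }
  total
}

# --- deterministic toy fitness/phenotype maps -----------------------------
# hash-based map over arbitrary strings: used for oracle-equivalence tests
# of the survey machinery on small alphabets
toy_map <- function(salt = 0L) {
  function(g) {
    codes <- utf8ToInt(g)
    h <- sum(codes * (seq_along(codes) + salt)) %% 101L
    list(fitness = 1 + (h %% 5L) / 10 - 0.2 * (h %% 3L == 0L),
         phenotype = paste0("P", h %% 4L),
         tasks = c(if (h %% 2L == 0L) "T_even",
                   if (h %% 5L == 0L) "T_five"))
  }
}

# brute-force one-step classification with the same map
oracle_one_step <- function(g, fn, alphabet, epsilon = 1e-9) {
  s <- strsplit(g, "")[[1]]
  parent <- fn(g)
  rows <- list()
  for (site in seq_along(s)) {
    for (a in alphabet) {
      if (a == s[site]) next
      m <- s
      m[site] <- a
      r <- fn(paste0(m, collapse = ""))
      rows[[length(rows) + 1]] <- data.frame(
        site = site, symbol = a, fitness = r$fitness,
        neutral = r$fitness >= parent$fitness * (1 - epsilon),
        preserving = r$phenotype == parent$phenotype,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# brute-force two-step regain fraction for task `task`
oracle_two_step <- function(g, fn, alphabet, task) {
  s0 <- strsplit(g, "")[[1]]
  parent <- fn(g)
  stopifnot(task %in% parent$tasks)
  n_tested <- 0L
  n_regain <- 0L
  n_lost <- 0L
  for (site in seq_along(s0)) {
    for (a in alphabet) {
      if (a == s0[site]) next
      m1 <- s0
      m1[site] <- a
      r1 <- fn(paste0(m1, collapse = ""))
      if (task %in% r1$tasks) next
      n_lost <- n_lost + 1L
      for (site2 in seq_along(s0)) {
        if (site2 == site) next # non-reversion rule
        for (b in alphabet) {
          if (b == m1[site2]) next
          m2 <- m1
          m2[site2] <- b
          r2 <- fn(paste0(m2, collapse = ""))
          n_tested <- n_tested + 1L
          if (task %in% r2$tasks) n_regain <- n_regain + 1L
        }
      }
    }
  }
  list(n_lost = n_lost, fraction = if (n_tested > 0) n_regain / n_tested
       else NA_real_)
}

# small task genome used across substrate tests (verified at build)
NAND_FIXTURE <- make_task_genome("NAND", l = 40, inputs = INS,
                                 catalog = CT3)
XE_FIXTURE <- make_task_genome(c("XOR", "EQU"), l = 60, inputs = INS,
                               catalog = CT3)
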
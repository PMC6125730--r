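test_that("mating follows the coercion threshold and the one-pass rule", {
  cfg <- tiny_config(xi = 0, zeta = 0)
  ## male mu = 5 on cell 1, female omega = 10 on adjacent cell 2: threshold
  ## mu >= omega fails, no attempt regardless of J
  gm <- flat_genome(0); gm[, 1:5] <- 1L   # mu = 5
  gf <- flat_genome(0); gf[, 21:25] <- 1L; gf[, 26:30] <- 1L # omega = 10
  pop <- hand_pop(rbind(gm, gf), c(FALSE, TRUE), c(1, 2))
  set.seed(1)
  mate <- mating_phase(pop, cfg)
  expect_equal(mate$x[2], 0L)
  expect_equal(mate$q[1], 0L)
  expect_equal(mate$h[2], 1L) # the male still counts as a neighbour
  ## mu = omega: the attempt occurs (>=, not >) and with xi = 0 it succeeds
  gm2 <- flat_genome(0); gm2[, 1:10] <- 1L # mu = 10
  pop2 <- hand_pop(rbind(gm2, gf), c(FALSE, TRUE), c(1, 2))
  set.seed(1)
  mate2 <- mating_phase(pop2, cfg)
  expect_equal(mate2$x[2], 1L)
  expect_equal(mate2$q[1], 1L)
  ## lone male with no neighbouring females: q stays 0
  pop3 <- hand_pop(gm, FALSE, 1)
  mate3 <- mating_phase(pop3, cfg)
  expect_equal(mate3$q, 0L)
  ## coevolution disabled: the threshold is never evaluated, so even a
  ## maximally resistant female is courted by a coercion-0 male
  gf20 <- flat_genome(0); gf20[, 21:40] <- 1L # omega = 20
  pop4 <- hand_pop(rbind(flat_genome(0), gf20), c(FALSE, TRUE), c(1, 2))
  cfg_off <- tiny_config(xi = 0, coevolution = FALSE)
  set.seed(2)
  expect_equal(mating_phase(pop4, cfg_off)$x[2], 1L)
  set.seed(2)
  expect_equal(mating_phase(pop4, cfg)$x[2], 0L)
})

test_that("each male attempts each neighbouring female at most once", {
  ## xi = 0 so every permitted attempt succeeds: x equals the number of
  ## neighbouring males, never more
  cfg <- tiny_config(xi = 0, coevolution = FALSE, n = 4)
  set.seed(4)
  k <- 16
  pop <- hand_pop(random_genomes(k), rep(c(TRUE, FALSE), k / 2),
                  sample.int(16, k))
  mate <- mating_phase(pop, cfg)
  expect_true(all(mate$x[pop$female] <= mate$h[pop$female]))
  expect_identical(mate$x[pop$female], mate$h[pop$female])
  expect_true(all(mate$q <= 8L))
  expect_true(all(mate$x <= 8L))
})

test_that("mated females use a single father for the whole brood", {
  cfg <- tiny_config(xi = 0, zeta = 0, m = 0, a = 8, kappa = 0)
  ## mother omega=0; two candidate fathers homozygous 0 vs homozygous 1 at
  ## all coercion loci -> each offspring's paternal coercion alleles are all
  ## 0 or all 1, and the whole brood must agree
  mo <- flat_genome(0)
  f0 <- flat_genome(0)
  f1 <- flat_genome(0); f1[, 1:20] <- 1L
  pop <- hand_pop(rbind(mo, f0, f1), c(TRUE, FALSE, FALSE), c(1, 2, 7))
  seen <- c(FALSE, FALSE)
  for (s in 1:12) {
    set.seed(s)
    mate <- mating_phase(pop, cfg)
    ## xi = 0 and omega = 0: both neighbouring males mate with her
    expect_equal(mate$x[1], 2L)
    off <- reproduction_phase(pop, mate, d = 0, cfg)
    expect_equal(nrow(off$G), 8L) # W = a = 8 (m = 0, zeta = 0)
    paternal_coercion <- rowSums(off$G[, seq(2, 20, by = 2), drop = FALSE])
    expect_true(all(paternal_coercion == 0L) || all(paternal_coercion == 10L))
    seen[(paternal_coercion[1] == 10L) + 1L] <- TRUE
  }
  ## over 12 seeds both fathers get chosen at least once
  expect_true(all(seen))
})

test_that("unmated females reproduce per genotype: pp nothing, mutants daughters", {
  cfg <- tiny_config(epsilon = 1, zeta = 0, a = 8, kappa = 0)
  ## unmated pp female -> 0 offspring
  pop <- hand_pop(flat_genome(0), TRUE, 1)
  mate <- list(x = 0L, q = 0L, h = 0L, partners = list(NULL))
  off <- reproduction_phase(pop, mate, d = 0, cfg)
  expect_equal(nrow(off$G), 0L)
  ## unmated PP female, epsilon=1, d=0, zeta=0, a=8 -> 8 daughters
  popP <- hand_pop(flat_genome(0, P_dosage = 2), TRUE, 1)
  set.seed(1)
  offP <- reproduction_phase(popP, mate, d = 0, cfg)
  expect_equal(nrow(offP$G), 8L)
  expect_true(all(offP$female))
  expect_true(all(offP$G[, 41:42] == 1L)) # PP mother is homozygous at locus 21
})

test_that("dispersal is binomial with uniform neighbour choice", {
  cfg <- tiny_config(gamma = 0)
  pools <- lapply(1:8, function(i) list(G = random_genomes(10),
                                        female = rep(TRUE, 10)))
  expect_identical(dispersal_phase(pools, rep(TRUE, 8), cfg), pools)
  ## gamma = 1 from habitat 0: every offspring moves to habitat 1
  cfg1 <- tiny_config(gamma = 1)
  pools0 <- c(list(list(G = random_genomes(20), female = rep(TRUE, 20))),
              lapply(2:8, function(i) list(G = random_genomes(0),
                                           female = logical(0))))
  set.seed(5)
  out <- dispersal_phase(pools0, rep(TRUE, 8), cfg1)
  expect_equal(nrow(out[[1]]$G), 0L)
  expect_equal(nrow(out[[2]]$G), 20L)
  ## interior habitat, gamma = 0.3: migrant count ~ Binomial(k, gamma),
  ## split evenly between the two sides (checked within 4 SE over many seeds)
  cfg3 <- tiny_config(gamma = 0.3)
  k <- 200; reps <- 60
  left <- right <- stay <- 0
  set.seed(6)
  for (r in seq_len(reps)) {
    pools3 <- lapply(1:8, function(i) {
      if (i == 4) list(G = random_genomes(k), female = rep(TRUE, k))
      else list(G = random_genomes(0), female = logical(0))
    })
    out <- dispersal_phase(pools3, rep(TRUE, 8), cfg3)
    left <- left + nrow(out[[3]]$G)
    right <- right + nrow(out[[5]]$G)
    stay <- stay + nrow(out[[4]]$G)
  }
  tot <- k * reps
  expect_lt(abs((left + right) / tot - 0.3), 4 * sqrt(0.3 * 0.7 / tot))
  expect_lt(abs(left / (left + right) - 0.5), 4 * sqrt(0.25 / (left + right)))
  expect_equal(left + right + stay, tot)
  ## lethal glaciated terrain: dispersers into an uninhabitable habitat die
  set.seed(7)
  habitable <- c(TRUE, rep(FALSE, 7))
  out <- dispersal_phase(pools0, habitable, cfg1) # gamma = 1 from habitat 0
  expect_equal(sum(sapply(out, function(p) nrow(p$G))), 0L)
  ## non-lethal toggle: with no habitable neighbour, offspring stay home
  cfgnl <- tiny_config(gamma = 1, dispersal_lethal = FALSE)
  set.seed(8)
  out <- dispersal_phase(pools0, habitable, cfgnl)
  expect_equal(nrow(out[[1]]$G), 20L)
})

test_that("recruitment culls uniformly to N and fills distinct patches", {
  cfg <- tiny_config(n = 20) # N = 400
  set.seed(9)
  mp <- build_metapopulation(cfg)
  pools <- lapply(1:8, function(i) {
    k <- c(600, 250, 0, 400, 10, 5, 1, 399)[i]
    list(G = random_genomes(k), female = rep(TRUE, k))
  })
  mp <- recruitment_phase(mp, pools)
  counts <- sapply(mp$pops, function(p) nrow(p$G))
  expect_equal(counts, c(400L, 250L, 0L, 400L, 10L, 5L, 1L, 399L))
  for (p in mp$pops) {
    expect_false(anyDuplicated(p$cell) > 0)
    expect_true(all(p$cell >= 1 & p$cell <= 400))
  }
})

test_that("the run schedule pulses P at the end of the burn-in", {
  ## before the pulse generation the metapopulation is pure pp; from the
  ## pulse generation onwards P segregates
  cfg2 <- tiny_config(n = 6, generations = 10, burn_in = 10)
  sim2 <- run_simulation(cfg2)
  s2 <- sim2$summary
  pre <- s2$generation < 10 & s2$count > 0
  expect_true(all(s2$P_freq[pre] == 0))
  fin <- final_state(sim2)
  expect_gt(sum(fin$P_freq * fin$count, na.rm = TRUE), 0)
  ## deglaciation happens at the same generation: with a small refuge the
  ## outer habitats can only be colonized after burn_in
  cfg3 <- tiny_config(n = 6, generations = 12, burn_in = 6, refuge = "small",
                      gamma = 0.3)
  sim3 <- run_simulation(cfg3)
  s <- sim3$summary
  expect_true(all(s$count[s$habitat > 0 & s$generation < 6] == 0))
})

test_that("generations = 0 returns only the initial state", {
  cfg <- tiny_config(n = 5, generations = 0)
  sim <- run_simulation(cfg)
  expect_equal(unique(sim$summary$generation), 0L)
  expect_equal(nrow(sim$summary), 8L)
})

test_that("identical seeds give bitwise-identical simulations", {
  cfg <- tiny_config(n = 8, generations = 25, burn_in = 8, gamma = 0.2)
  s1 <- run_simulation(cfg)
  s2 <- run_simulation(cfg)
  expect_identical(s1$summary, s2$summary)
  expect_identical(s1$final, s2$final)
  ## a different seed gives a different trajectory
  cfg$seed <- 2L
  s3 <- run_simulation(cfg)
  expect_false(identical(s1$summary, s3$summary))
})

test_that("adult counts never exceed N and frequencies stay in [0, 1]", {
  for (cfg in list(tiny_config(n = 6, generations = 30, burn_in = 5,
                               gamma = 0.3, kappa = 0.7),
                   tiny_config(n = 6, generations = 30, burn_in = 5,
                               refuge = "small", epsilon = 1, seed = 3),
                   tiny_config(n = 6, generations = 30, burn_in = 5,
                               coevolution = FALSE, m = 0, seed = 4))) {
    sim <- run_simulation(cfg)
    s <- sim$summary
    expect_true(all(s$count <= 36))
    occupied <- s$count > 0
    for (col in c("sex_ratio", "coercion_freq", "resistance_freq", "P_freq")) {
      v <- s[[col]][occupied]
      expect_true(all(v >= 0 & v <= 1))
    }
  }
})

test_that("fitness diagnostics snapshots are recorded at requested generations", {
  cfg <- preset_config("fig5", n = 8, generations = 80, burn_in = 10,
                       diagnose_at = c(40L, 75L), seed = 2)
  sim <- run_simulation(cfg)
  expect_false(is.null(sim$diagnostics))
  expect_setequal(unique(sim$diagnostics$generation), c(40L, 75L))
  expect_true(all(c("omega_f", "genotype", "mated", "W", "habitat") %in%
                    names(sim$diagnostics)))
  expect_true(all(sim$diagnostics$W >= 0))
})

test_that("the neutral limit drifts around the mean-field recursion", {
  ## all costs off, flat environment, coevolution off, epsilon = 1, no
  ## dispersal: P is advantaged only through virgin reproduction (wild-type
  ## virgins are sterile). Independent oracle: a deterministic mean-field
  ## recursion on (proportion female, genotype frequencies) with the virgin
  ## probability computed from grid geometry at full occupancy.
  n <- 8
  virgin_prob <- function(phi) {
    (4 * phi^3 + 4 * (n - 2) * phi^5 + (n - 2)^2 * phi^8) / n^2
  }
  mean_field <- function(gens) {
    phi <- 0.5
    gf <- c(pp = 0.75, pP = 0.125, PP = 0.125) # post-pulse genotype freqs
    gm <- gf
    for (g in seq_len(gens)) {
      v <- virgin_prob(phi)
      pm <- gm[["pP"]] / 2 + gm[["PP"]] # P freq in sperm
      off_m <- c(pp = 0, pP = 0, PP = 0)
      for (gt in names(gf)) {
        pe <- c(pp = 0, pP = 0.5, PP = 1)[[gt]]
        off_m <- off_m + gf[[gt]] *
          c((1 - pe) * (1 - pm), (1 - pe) * pm + pe * (1 - pm), pe * pm)
      }
      off_v <- c(pp = gf[["pP"]] / 4, pP = gf[["pP"]] / 2,
                 PP = gf[["pP"]] / 4 + gf[["PP"]]) # automictic daughters
      wv <- v * (gf[["pP"]] + gf[["PP"]])
      wm <- 1 - v
      phi <- (0.5 * wm + wv) / (wm + wv)
      gf <- 0.5 * wm * off_m + wv * off_v
      gf <- gf / sum(gf)
      gm <- off_m
    }
    phi * (gf[["pP"]] / 2 + gf[["PP"]]) +
      (1 - phi) * (gm[["pP"]] / 2 + gm[["PP"]])
  }
  pred <- mean_field(30)
  pf <- sapply(1:16, function(k) {
    cfg <- sim_config(n = n, generations = 40, burn_in = 10, m = 0,
                      kappa = 0, zeta = 0, xi = 0, gamma = 0,
                      coevolution = FALSE, epsilon = 1, seed = k)
    f <- final_state(run_simulation(cfg))
    f$P_freq[f$habitat == 0]
  })
  se <- stats::sd(pf) / sqrt(length(pf))
  expect_lt(abs(mean(pf) - pred), 4 * se + 0.02)
  ## and the advantage is real: no systematic decline below the post-pulse
  ## allele frequency
  expect_gt(mean(pf), 0.1875 - 4 * se)
})
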
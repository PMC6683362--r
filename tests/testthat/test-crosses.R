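test_that("genotype construction enforces copy count and R X-linkage", {
  g <- frog_genotype(c("Rx", "Lx"))
  expect_identical(format(g), "LxRx")
  expect_identical(frog_sex(g), "F")
  expect_identical(genotype_class(g), "LR")
  expect_identical(frog_sex(parse_genotype("LyRx")), "M")
  expect_identical(genotype_class(parse_genotype("LxLyRx")), "LLR")
  expect_error(frog_genotype("Lx"), "2 or 3")
  expect_error(frog_genotype(c("Lx", "Ry")), "X-linked")
  expect_message(frog_genotype(c("Lx", "Ry"), allow_Ry = TRUE), "relaxed")
})

test_that("gamete distributions implement the hybridogenetic modes", {
  hyb_f <- parse_genotype("LxRx")
  expect_equal(gamete_distribution(hyb_f, gamete_rule("ELIMINATE_L")),
               c(Rx = 1))
  expect_equal(gamete_distribution(hyb_f, gamete_rule("ELIMINATE_R")),
               c(Lx = 1))
  expect_equal(gamete_distribution(parse_genotype("LyRx"),
                                   gamete_rule("AMPHI", q = 0.5)),
               c(Ly = 0.5, Rx = 0.5))
  expect_equal(gamete_distribution(parse_genotype("LxLy"),
                                   gamete_rule("MENDELIAN")),
               c(Lx = 0.5, Ly = 0.5))
  expect_equal(gamete_distribution(hyb_f, gamete_rule("DIPLOID_LR")),
               c(LxRx = 1))
  # triploid table: LLR gives recombined L haploids
  tri <- gamete_rule("TRIPLOID_RULE",
                     triploid_table = list(LLR = c(L_haploid = 0.5,
                                                   LL_unreduced = 0.5)))
  expect_equal(gamete_distribution(parse_genotype("LxLyRx"), tri),
               c(Lx = 0.25, LxLy = 0.5, Ly = 0.25))
  expect_error(gamete_distribution(parse_genotype("LxLy"),
                                   gamete_rule("ELIMINATE_L")),
               "not applicable")
})

test_that("gamete distributions sum to one for every preset-reachable case", {
  cases <- list(
    list(sys = "L_E", g = c("LxRx", "LyRx", "LxLx", "LxLy")),
    list(sys = "R_E", g = c("LxRx", "LyRx", "RxRx")),
    list(sys = "E_E_TRIPLOID", g = c("LxRx", "LyRx", "LxLyRx", "LxRxRx")),
    list(sys = "E_E_DIPLOID_AMPHIGAMY", g = c("LxRx", "LyRx")))
  for (cs in cases) {
    sys <- system_preset(cs$sys)
    for (gs in cs$g) {
      g <- parse_genotype(gs)
      d <- gamete_distribution(g, rule_for(sys, g))
      expect_equal(sum(d), 1)
    }
  }
})

test_that("the L-E backcross and inter-hybrid cross match the system model", {
  le <- system_preset("L_E")
  # hybrid female x parental LL male: half female, half male hybrids
  bc <- cross(parse_genotype("LxRx"), parse_genotype("LxLy"), system = le)
  expect_equal(bc$p_pre[match(c("LxRx", "LyRx"), bc$genotype)], c(0.5, 0.5))
  expect_identical(bc$sex[match(c("LxRx", "LyRx"), bc$genotype)], c("F", "M"))
  expect_equal(bc$p_post, bc$p_pre)   # all hybrid offspring viable
  # inter-hybrid cross: clonal R eggs meet clonal R sperm, all-RR zygotes,
  # none viable under hybridogenetic load
  ih <- cross(parse_genotype("LxRx"), parse_genotype("LyRx"), system = le)
  expect_equal(nrow(ih), 1L)
  expect_identical(ih$genotype, "RxRx")
  expect_equal(ih$p_pre, 1)
  expect_equal(ih$p_post, 0)
})

test_that("diploid amphigamy gives the 2x2 Punnett quartet with sex linkage", {
  ee <- system_preset("E_E_DIPLOID_AMPHIGAMY")
  cr <- cross(parse_genotype("LxRx"), parse_genotype("LyRx"), system = ee)
  expect_identical(cr$genotype, c("LxLy", "LxRx", "LyRx", "RxRx"))
  expect_equal(cr$p_pre, rep(0.25, 4))
  # every RR offspring is female, every LL offspring male
  expect_identical(cr$sex[cr$class == "RR"], "F")
  expect_identical(cr$sex[cr$class == "LL"], "M")
  # load removes the homotypic quarter; hybrids renormalize to 1/2 each
  expect_equal(cr$p_post[cr$class == "LR"], c(0.5, 0.5))
  expect_equal(cr$p_post[cr$class %in% c("LL", "RR")], c(0, 0))
})

test_that("the mixed-ploidy all-hybrid preset builds triploids from LR eggs", {
  et <- system_preset("E_E_TRIPLOID")
  # unreduced LR egg + hemiclonal R sperm -> LRR triploid
  cr <- cross(parse_genotype("LxRx"), parse_genotype("LyRx"), system = et)
  expect_identical(cr$genotype, "LxRxRx")
  expect_identical(cr$class, "LRR")
  # unreduced LR egg + recombined L sperm from an LLR male -> LLR, both sexes
  cr2 <- cross(parse_genotype("LxRx"), parse_genotype("LxLyRx"), system = et)
  expect_identical(sort(cr2$genotype), c("LxLxRx", "LxLyRx"))
  expect_equal(cr2$p_pre, c(0.5, 0.5))
})

test_that("cross results equal the independent gamete-pair enumeration", {
  configs <- list(
    list(m = "LxRx", f = "LxLy", sys = "L_E"),
    list(m = "LxRx", f = "LyRx", sys = "L_E"),
    list(m = "LxLx", f = "LxLy", sys = "L_E"),
    list(m = "LxRx", f = "LyRx", sys = "R_E"),
    list(m = "RxRx", f = "LyRx", sys = "R_E"),
    list(m = "LxRx", f = "LyRx", sys = "E_E_DIPLOID_AMPHIGAMY"),
    list(m = "LxRx", f = "LyRx", sys = "E_E_TRIPLOID"),
    list(m = "LxRx", f = "LxLyRx", sys = "E_E_TRIPLOID"),
    list(m = "LxRxRx", f = "LyRx", sys = "E_E_TRIPLOID"))
  for (cf in configs) {
    sys <- system_preset(cf$sys)
    m <- parse_genotype(cf$m); f <- parse_genotype(cf$f)
    got <- cross(m, f, system = sys)
    want <- oracle_cross_pre(gamete_distribution(m, rule_for(sys, m)),
                             gamete_distribution(f, rule_for(sys, f)))
    expect_identical(got$genotype, names(want))
    expect_equal(got$p_pre, unname(want))
    expect_equal(sum(got$p_pre), 1)
  }
})

test_that("sex roles are enforced", {
  expect_error(cross(parse_genotype("LyRx"), parse_genotype("LxLy"),
                     system = system_preset("L_E")), "female")
  expect_error(cross(parse_genotype("LxRx"), parse_genotype("LxRx"),
                     system = system_preset("L_E")), "male")
})

test_that("unknown presets are rejected with the preset list", {
  expect_error(system_preset("X_E"), "available")
})

test_that("L-E recursion never retains homotypic RR and keeps hybrids hosted", {
  le <- system_preset("L_E")
  traj <- iterate_generations(le, c(LxRx = 0.3, LxLx = 0.4, LxLy = 0.3), 5)
  for (gen in traj) {
    cls <- vapply(names(gen), function(k)
      genotype_class(parse_genotype(k)), character(1))
    expect_true(all(gen[cls == "RR"] == 0))
    expect_true(sum(gen[cls == "LR"]) >= 0 && abs(sum(gen) - 1) < 1e-12)
  }
  # hybrid-involved crosses never yield LL under L-E rules
  for (mother in c("LxRx")) {
    for (father in c("LxLy", "LyRx")) {
      cr <- cross(parse_genotype(mother), parse_genotype(father), system = le)
      expect_false("LL" %in% cr$class)
    }
  }
  # female hybrid x male LL is the only cross producing sons and daughters;
  # LL x LL keeps the host species going
  host <- cross(parse_genotype("LxLx"), parse_genotype("LxLy"), system = le)
  expect_equal(sum(host$p_post), 1)
})

test_that("amphigamy recursion reaches the all-hybrid equilibrium", {
  ee <- system_preset("E_E_DIPLOID_AMPHIGAMY")
  traj <- iterate_generations(ee, c(LxRx = 0.7, LyRx = 0.3), 6)
  final <- traj[[7]]
  expect_equal(unname(final["LxRx"]), 0.5)
  expect_equal(unname(final["LyRx"]), 0.5)
  cls <- vapply(names(final), function(k)
    genotype_class(parse_genotype(k)), character(1))
  expect_true(all(final[cls %in% c("LL", "RR")] == 0))
})
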
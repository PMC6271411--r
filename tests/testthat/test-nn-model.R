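test_that("the study 13-mer validates for all six X.Y variants", {
  for (xy in c("G.C", "D.T", "I.C", "A.T", "G.T", "I.T")) {
    d <- study_duplex(xy)
    expect_equal(d$length, 13)
    expect_equal(d$pairs[9], xy)
    # every other position is Watson-Crick
    expect_true(all(d$pairs[-9] %in% c("A.T", "G.C")))
  }
})

test_that("duplex validation rejects malformed input", {
  expect_error(validate_duplex("AAA", "TTTT"), "length")
  expect_error(validate_duplex("AT", "AT"), "self-complementary")
  expect_error(validate_duplex("AGA", "TGT"), "not a recognised pair")  # I.G analog: G.G
  expect_error(validate_duplex("AIA", "TGT"), "not a recognised pair")  # I.G
  expect_error(validate_duplex("AXA", "TTT"), "unrecognised bases")
  expect_error(validate_duplex("", ""), "non-empty")
})

test_that("the nearest-neighbor table is symmetric and complete", {
  tab <- nn_table()
  expect_equal(sum(tab$steps$set == "WC"), 10)
  expect_equal(sum(tab$steps$set == "GT"), 11)
  # every step equals its reverse-complement written form
  alt <- function(key) {
    ch <- strsplit(key, "")[[1]]
    paste0(ch[5], ch[4], "/", ch[2], ch[1])
  }
  for (i in seq_len(nrow(tab$steps))) {
    k <- tab$steps$key[i]
    a <- duplexmelt:::nn_step(alt(k))
    expect_equal(a$dH, tab$steps$dH[i])
    expect_equal(a$dS, tab$steps$dS[i])
  }
  expect_match(tab$provenance, "SantaLucia")
})

test_that("nn_predict equals an independent hand summation of steps plus initiation", {
  d <- study_duplex("A.T")
  pred <- nn_predict(d)
  # oracle: enumerate the 12 steps of TTTGTATCACAAT/ATTGTGATACAAA by hand
  # and sum straight out of the published table
  keys <- c("TT/AA", "TT/AA", "TG/AC", "GT/CA", "TA/AT", "AT/TA",
            "TC/AG", "CA/GT", "AC/TG", "CA/GT", "AA/TT", "AT/TA")
  tab <- nn_table()$steps
  canon <- function(k) {
    if (k %in% tab$key) k else {
      ch <- strsplit(k, "")[[1]]
      paste0(ch[5], ch[4], "/", ch[2], ch[1])
    }
  }
  dH <- sum(sapply(keys, function(k) tab$dH[tab$key == canon(k)]))
  dS <- sum(sapply(keys, function(k) tab$dS[tab$key == canon(k)]))
  init <- nn_table()$initiation
  dH <- dH + 2 * init$AT$dH   # both terminal pairs are A.T
  dS <- dS + 2 * init$AT$dS
  expect_equal(pred$dH, dH, tolerance = 1e-12)
  expect_equal(pred$dS, dS, tolerance = 1e-12)
  # frozen totals from that enumeration
  expect_equal(pred$dH, -91.2)
  expect_equal(pred$dS, -255.6)
})

test_that("nn_predict is invariant under swapping strands and rejects I/D", {
  d <- study_duplex("G.C")
  sw <- validate_duplex(d$bottom, d$top)
  expect_equal(nn_predict(sw)$dH, nn_predict(d)$dH, tolerance = 1e-12)
  expect_equal(nn_predict(sw)$dS, nn_predict(d)$dS, tolerance = 1e-12)
  expect_error(nn_predict(study_duplex("I.C")), "I or D")
  expect_error(nn_predict(study_duplex("D.T")), "I or D")
  # terminal wobble has no initiation parameters
  expect_error(nn_predict(validate_duplex("GAC", "GTT")), "terminal")
})

test_that("a 2-mer duplex is one step plus two initiation terms", {
  d <- validate_duplex("GA", "TC")
  pred <- nn_predict(d)
  tab <- nn_table()
  expect_equal(pred$dH, tab$steps$dH[tab$steps$key == "GA/CT"] +
                 tab$initiation$GC$dH + tab$initiation$AT$dH,
               tolerance = 1e-12)
  expect_equal(pred$dS, tab$steps$dS[tab$steps$key == "GA/CT"] +
                 tab$initiation$GC$dS + tab$initiation$AT$dS,
               tolerance = 1e-12)
})

test_that("wobble trinucleotide core reproduces the published prediction", {
  tri <- nn_trinucleotide("CGC", "GTG")
  expect_equal(-tri$dG37, 1.06, tolerance = 0.005)
  expect_equal(-tri$dH, 8.5, tolerance = 1e-12)
  # the entropy consistent with the dH/dG37 pair at 310.15 K
  expect_equal(-tri$dS, 24.0, tolerance = 1e-12)
  # written from the other strand, same values
  tri2 <- nn_trinucleotide("GTG", "CGC")
  expect_equal(tri2$dH, tri$dH)
  expect_equal(tri2$dS, tri$dS)
  expect_error(nn_trinucleotide("CGCG", "GTG"), "3-mer")
  expect_error(nn_trinucleotide("TGT", "AGA"), "Watson-Crick|recognised")
})

test_that("trinucleotide additivity: full prediction minus non-central steps equals the core", {
  d <- study_duplex("G.T")
  # build the same duplex with X=G, Y=T but measured = NN prediction is not
  # available (G.T internal steps ARE available), so check the identity on
  # the all-Watson-Crick variant first
  dwc <- study_duplex("G.C")
  measured <- nn_predict(dwc)
  core <- trinucleotide_core_from_measured(measured, dwc, center = 9)
  tri <- nn_trinucleotide(substr(dwc$top, 8, 10),
                          substr(dwc$bottom, 4, 6))
  expect_equal(core$dH, tri$dH, tolerance = 1e-10)
  expect_equal(core$dS, tri$dS, tolerance = 1e-10)
  # same identity through the wobble duplex, whose steps are published too
  measured_gt <- nn_predict(d)
  core_gt <- trinucleotide_core_from_measured(measured_gt, d, center = 9)
  tri_gt <- nn_trinucleotide(substr(d$top, 8, 10), substr(d$bottom, 4, 6))
  expect_equal(core_gt$dH, tri_gt$dH, tolerance = 1e-10)
  expect_equal(core_gt$dS, tri_gt$dS, tolerance = 1e-10)
  # linearity: perturbing the measured input shifts the core one-for-one
  bumped <- thermo_params(measured$dH + 0.5, measured$dS)
  core_b <- trinucleotide_core_from_measured(bumped, dwc, center = 9)
  expect_equal(core_b$dH - core$dH, 0.5, tolerance = 1e-12)
  expect_equal(core_b$dG37 - core$dG37, 0.5, tolerance = 1e-12)
  expect_error(trinucleotide_core_from_measured(measured, dwc, center = 1),
               "interior")
})

test_that("measured cores preserve the duplex stability ordering", {
  # identical flanks mean the core is the measured value minus one constant,
  # so the published stability order must survive the subtraction
  stab <- published_duplex_stability()
  cores <- sapply(seq_len(nrow(stab)), function(i) {
    d <- study_duplex(stab$pair[i])
    measured <- thermo_params(-95, (-95 + stab$minus_dG37_1M[i]) * 1000 / 310.15)
    -trinucleotide_core_from_measured(measured, d, center = 9)$dG37
  })
  expect_identical(order(cores, decreasing = TRUE),
                   order(stab$minus_dG37_1M, decreasing = TRUE))
  expect_true(all(diff(cores) <= 0))  # table already in stability order
})
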
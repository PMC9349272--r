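toy_genes <- function() {
  data.frame(gene = c("G1", "G2", "G3"),
             chr = c(1, 1, 2),
             strand = c("+", "-", "+"),
             tss = c(100000, 150000, 50000),
             start = c(100000, 130000, 50000),
             end = c(120000, 150000, 70000),
             stringsAsFactors = FALSE)
}

test_that("regulatory domains follow the basal-plus-extension arithmetic", {
  g <- toy_genes()[3, ]  # isolated + strand gene, TSS 50,000
  d <- build_domains(g)
  expect_equal(d$basal_start, 45000)
  expect_equal(d$basal_end, 51000)
  expect_equal(d$domain_start, 40000)
  expect_equal(d$domain_end, 56000)
  # isolated + strand gene at TSS 100,000: basal [95,000, 101,000] extended
  # 5 kb each way -> [90,000, 106,000]
  iso <- data.frame(gene = "X", chr = 9, strand = "+", tss = 100000,
                    start = 100000, end = 110000)
  di <- build_domains(iso)
  expect_equal(c(di$basal_start, di$basal_end), c(95000, 101000))
  expect_equal(c(di$domain_start, di$domain_end), c(90000, 106000))
  # minus strand mirrors the plus strand under reflection
  iso_m <- transform(iso, strand = "-")
  dm <- build_domains(iso_m)
  expect_equal(dm$basal_start, 100000 - 1000)
  expect_equal(dm$basal_end, 100000 + 5000)
  expect_equal(dm$domain_end - dm$tss, -(di$domain_start - di$tss))
  # clipping at chromosome start
  near0 <- data.frame(gene = "Y", chr = 1, strand = "+", tss = 2000,
                      start = 2000, end = 9000)
  expect_equal(build_domains(near0)$domain_start, 1)
})

test_that("extensions stop at a neighbouring basal domain", {
  # two + strand genes whose basal domains end 2 kb apart
  gg <- data.frame(gene = c("A", "B"), chr = 1, strand = "+",
                   tss = c(100000, 108000),
                   start = c(100000, 108000), end = c(100500, 108500))
  d <- build_domains(gg)
  # A basal [95,000, 101,000]; B basal [103,000, 109,000]
  expect_equal(d$domain_end[d$gene == "A"], 102999)
  expect_equal(d$domain_start[d$gene == "B"], 101001)
  # no extension invades a disjoint neighbouring basal domain, random layouts
  overlaps <- function(a1, a2, b1, b2) a1 <= b2 && a2 >= b1
  set.seed(7)
  for (i in 1:5) {
    n <- 12
    rg <- data.frame(gene = sprintf("R%02d", 1:n), chr = sample(1:2, n, TRUE),
                     strand = sample(c("+", "-"), n, TRUE),
                     tss = sample.int(4e5, n))
    rg$start <- pmax(rg$tss - 5000, 1); rg$end <- rg$tss + 5000
    dd <- build_domains(rg)
    for (a in seq_len(n)) for (b in seq_len(n)) {
      if (a == b || dd$chr[a] != dd$chr[b]) next
      if (overlaps(dd$basal_start[a], dd$basal_end[a],
                   dd$basal_start[b], dd$basal_end[b])) next
      if (dd$domain_start[a] < dd$basal_start[a])  # left extension
        expect_false(overlaps(dd$domain_start[a], dd$basal_start[a] - 1,
                              dd$basal_start[b], dd$basal_end[b]))
      if (dd$domain_end[a] > dd$basal_end[a])      # right extension
        expect_false(overlaps(dd$basal_end[a] + 1, dd$domain_end[a],
                              dd$basal_start[b], dd$basal_end[b]))
    }
  }
  expect_warning(build_domains(rbind(gg, gg[1, ])), "duplicate")
})

test_that("probe mapping matches hand enumeration on a toy layout", {
  genes <- rbind(toy_genes(),
                 data.frame(gene = "G4", chr = 1, strand = "+", tss = 119000,
                            start = 119000, end = 125000))
  doms <- build_domains(genes)
  # enumerated domains:
  #   G1 (+, tss 100,000, body 100,000-120,000): basal [95,000, 101,000],
  #       domain [90,000, 106,000] (right extension stops well before G4)
  #   G2 (-, tss 150,000, body 130,000-150,000): basal [149,000, 155,000],
  #       domain [144,000, 160,000]
  #   G4 (+, tss 119,000, body 119,000-125,000): basal [114,000, 120,000],
  #       domain [109,000, 125,000]
  #   G3 (+, chr2, tss 50,000, body 50,000-70,000): basal [45,000, 51,000],
  #       domain [40,000, 56,000]
  expect_equal(doms$domain_start[doms$gene == "G1"], 90000)
  expect_equal(doms$domain_end[doms$gene == "G1"], 106000)
  expect_equal(doms$domain_start[doms$gene == "G4"], 109000)
  probes <- data.frame(
    probe_id = sprintf("cg%d", 1:8),
    chr = c(1, 1, 1, 1, 1, 2, 2, 3),
    pos = c(98000,   # G1 basal only: regulatory, not physical
            110000,  # G1 body; inside G4's left extension
            119500,  # G1 body + G4 body/basal: multi-gene
            149500,  # G2 body + basal
            165000,  # beyond every domain: no hit
            51000,   # G3 body + basal
            70000,   # G3 body, beyond its domain
            51000))  # wrong chromosome
  phys <- map_probes(probes, genes, doms, mode = "physical")
  expect_setequal(phys$pairs$probe_id[phys$pairs$gene == "G1"],
                  c("cg2", "cg3"))
  expect_false("cg1" %in% phys$pairs$probe_id)
  reg <- map_probes(probes, genes, doms, mode = "regulatory")
  expect_setequal(reg$pairs$gene[reg$pairs$probe_id == "cg1"], "G1")
  expect_setequal(reg$pairs$gene[reg$pairs$probe_id == "cg2"], "G4")
  uni <- map_probes(probes, genes, doms, mode = "union")
  # multi-mapping retained: cg3 reaches both G1 (body) and G4 (body+basal)
  expect_setequal(uni$pairs$gene[uni$pairs$probe_id == "cg3"], c("G1", "G4"))
  expect_true(all(phys$pairs$probe_id %in% uni$pairs$probe_id))
  expect_true(all(reg$pairs$probe_id %in% uni$pairs$probe_id))
  expect_false(any(c("cg5", "cg8") %in% uni$pairs$probe_id))
  expect_setequal(uni$pairs$gene[uni$pairs$probe_id == "cg7"], "G3")
  expect_error(map_probes(probes, genes, mode = "regulatory"), "domains")
})

test_that("GMT round-trips and enrichment matches exact combinatorics", {
  gmt <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tG1\tG2\tG3", "setB\tdesc\tG4\tG5"), gmt)
  sets <- read_gmt(gmt)
  expect_equal(sets, list(setA = c("G1", "G2", "G3"), setB = c("G4", "G5")))

  bg <- sprintf("G%02d", 1:20)
  # full-overlap draw: p = 1/choose(20,5)
  res <- enrich_gene_sets(bg[1:5], list(s = bg[1:5]), bg)
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12)
  # query = background: every set has p = 1
  res2 <- enrich_gene_sets(bg, list(s1 = bg[1:5], s2 = bg[3:9]), bg)
  expect_true(all(res2$p == 1))
  # overlap at expectation is unremarkable (p >= 0.5)
  res3 <- enrich_gene_sets(bg[1:10], list(s = bg[seq(1, 20, 2)]), bg)
  expect_gte(res3$p, 0.5)
  expect_error(enrich_gene_sets("G01", list(s = "G01"), character(0)), "background")
  expect_true(all(res2$p_adj >= res2$p))
})

test_that("hypergeometric p equals exhaustive enumeration for small universes", {
  set.seed(8)
  for (i in 1:6) {
    N <- sample(10:25, 1)
    K <- sample(2:(N - 2), 1)
    n <- sample(2:(N - 2), 1)
    bg <- sprintf("g%02d", 1:N)
    q <- sample(bg, n)
    res <- enrich_gene_sets(q, list(s = bg[1:K]), bg)
    expect_equal(res$p, brute_hyper_p(N, K, n, res$overlap), tolerance = 1e-12)
  }
})
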
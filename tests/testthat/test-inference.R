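tm_default <- default_taxon_map()

annotate <- function(nwk) assign_taxa(read_gene_tree(nwk), tm_default)

test_that("is_spanning requires genes from both sides, ignoring algae", {
  tr <- annotate("(((Pp1,At1)90,(Sm1,(Os1,At2)80)70)60,Cr1);")
  n <- length(tr$tip.label)
  sets <- copymin:::node_leafsets(tr)
  # moss + eudicot cherry spans
  cherry <- which(vapply(sets, function(s)
    setequal(tr$tip.label[s], c("Pp1", "At1")), logical(1)))
  expect_true(is_spanning(tr, cherry))
  # lycophyte + monocot + eudicot clade has no moss: not spanning
  blue <- which(vapply(sets, function(s)
    setequal(tr$tip.label[s], c("Sm1", "Os1", "At2")), logical(1)))
  expect_false(is_spanning(tr, blue))
  # a lone algal leaf never spans
  expect_false(is_spanning(tr, match("Cr1", tr$tip.label)))
})

test_that("a fully resolved moss-sister topology counts one ancestral copy", {
  tr <- annotate("((Pp1,Pp2)95,(Sm1,(Os1,At1)90)88);")
  for (m in c("paper", "strict")) {
    r <- min_ancestral_copies(tr, mode = m)
    expect_equal(r$min_copies, 1L)
    expect_false(r$nd)
    expect_equal(nrow(clade_report(r)), 1)
  }
})

test_that("a moss/eudicot cherry counts one copy", {
  tr <- annotate("(Pp1,At1);")
  expect_equal(min_ancestral_copies(tr)$min_copies, 1L)
})

test_that("spanning clades and mixed polytomy leftovers are counted per mode", {
  # two resolved spanning clades + loose moss and angiosperm leaves at root
  tr <- annotate(paste0("((Pp1,(Sm1,At1)90)80,((Pp2,Pp3)85,(Os1,At2)75)70,",
                        "Pp9,At9);"))
  rp <- min_ancestral_copies(tr, mode = "paper")
  rs <- min_ancestral_copies(tr, mode = "strict")
  expect_equal(rp$min_copies, 3L) # 2 clades + 1 polytomy bonus
  expect_equal(rs$min_copies, 2L) # strict mode: no leftover bonus
  expect_equal(nrow(rp$spanning_clades), 2)
  expect_equal(nrow(rp$bonus_nodes), 1)
  expect_equal(nrow(rs$bonus_nodes), 0)
})

test_that("families absent on one side of the split are ND", {
  no_moss <- annotate("((At1,At2)90,(Os1,Sb1)85);")
  r <- min_ancestral_copies(no_moss)
  expect_true(r$nd)
  expect_true(is.na(r$min_copies))
  rep <- clade_report(r)
  expect_equal(nrow(rep), 0)
  expect_true(attr(rep, "nd"))
  no_tracheo <- annotate("((Pp1,Pp2)90,Pp3);")
  expect_true(min_ancestral_copies(no_tracheo)$nd)
  # an algae-only tree is an error, not ND
  expect_error(min_ancestral_copies(annotate("(Cr1,(Sp1,Nh1));")),
               "outgroup")
})

test_that("paper mode equals the brute-force minimal-spanning-node count on binary trees", {
  set.seed(314)
  checked <- 0
  while (checked < 300) {
    tr <- random_annotated_tree(sample(4:10, 1))
    side <- split_sides_of(tr)
    if (!any(side == "A", na.rm = TRUE) || !any(side == "B", na.rm = TRUE)) next
    want <- oracle_min_spanning(tr, side)
    expect_equal(min_ancestral_copies(tr, mode = "paper")$min_copies, want)
    expect_equal(min_ancestral_copies(tr, mode = "strict")$min_copies, want)
    checked <- checked + 1
  }
})

test_that("strict mode never exceeds paper mode, including on polytomies", {
  set.seed(2718)
  checked <- 0
  while (checked < 100) {
    tr <- random_annotated_tree(sample(6:14, 1))
    side <- split_sides_of(tr)
    if (!any(side == "A", na.rm = TRUE) || !any(side == "B", na.rm = TRUE)) next
    # collapse random supports to create polytomies
    tr$node.label <- c("", as.character(sample(0:100, tr$Nnode - 1, TRUE)))
    ct <- collapse_low_support(as_gene_tree(tr), 50)
    rp <- min_ancestral_copies(ct, mode = "paper")$min_copies
    rs <- min_ancestral_copies(ct, mode = "strict")$min_copies
    expect_lte(rs, rp)
    checked <- checked + 1
  }
})

test_that("adding a leaf inside an existing spanning clade never changes the count", {
  base <- "((Pp1,(Sm1,At1)90)80,((Pp2,Pp3)85,(Os1,At2)75)70,Pp9,At9);"
  r0 <- min_ancestral_copies(annotate(base))
  grown <- list(
    # extra eudicot inside first spanning clade
    "((Pp1,(Sm1,(At1,At3)99)90)80,((Pp2,Pp3)85,(Os1,At2)75)70,Pp9,At9);",
    # extra moss inside second spanning clade
    "((Pp1,(Sm1,At1)90)80,((Pp2,(Pp3,Pp4)99)85,(Os1,At2)75)70,Pp9,At9);"
  )
  for (nwk in grown) {
    expect_equal(min_ancestral_copies(annotate(nwk))$min_copies,
                 r0$min_copies, info = nwk)
  }
})

test_that("clade reports carry composition, support and uncounted B-only clades", {
  fx <- make_figure_fixtures()
  gaut <- analyze_tree(fx[["Galacturonosyltransferases (GAUTs)"]], tm_default,
                       family = "GAUT")
  rep <- clade_report(gaut)
  expect_equal(sum(rep$counted), 3)
  expect_equal(sum(rep$type == "clade"), 2)
  expect_equal(sum(rep$type == "bonus"), 1)
  # the moss-free clade is surfaced but not counted
  expect_equal(sum(rep$type == "b_only"), 1)
  expect_true(all(rep$n_side_a[rep$type == "clade"] >= 1))
  expect_true(all(rep$n_side_b[rep$type == "clade"] >= 1))
  expect_true(all(rep$support[rep$type == "clade"] == 100))
  g <- glance(gaut)
  expect_equal(g$min_copies, 3L)
  expect_equal(g$n_uncounted_b_only, 1L)
  expect_identical(tidy(gaut), rep)
})

test_that("the focal split generalises to monocot vs eudicot", {
  tr <- annotate("((Os1,At1)90,((Os2,Sb1)85,(At2,Mt1)80)70,Pp1);")
  r <- min_ancestral_copies(tr, split = focal_split("monocot", "eudicot"))
  # two spanning children of the root; the moss leftover is outside this
  # split so no polytomy bonus
  expect_equal(r$min_copies, 2L)
})

test_that("autoplot returns a ggplot for counts and for ND", {
  fx <- make_figure_fixtures()
  r <- analyze_tree(fx[["Polygalacturonases"]], tm_default)
  expect_s3_class(autoplot(r), "ggplot")
  nd <- suppressWarnings(analyze_tree(
    fx[["Pectin methylesterase inhibitors (PMEIs)"]], tm_default))
  expect_s3_class(autoplot(nd), "ggplot")
})
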
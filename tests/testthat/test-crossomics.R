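make_rna <- function(mat) rna_table(mat)

test_that("RNA specificity rule: flooring, log2 ratio, boundary convention", {
  m <- rbind(g1 = c(16, 2, 2, 2, 2),    # log2 4 vs mean 1 -> specific
             g2 = c(4, 2, 2, 2, 2),     # log2 2 vs mean 1 -> boundary, specific
             g3 = c(0.5, 0.9, 0.2, 0.4, 0.8),  # all floored -> not specific
             g4 = c(3, 2, 2, 2, 2))     # log2 1.58 < 2 -> not specific
  colnames(m) <- c("Cx", "CB", "BS", "HIP", "THA_HT")
  calls <- rna_specificity(make_rna(m))
  expect_equal(calls$specific, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(calls$max_region[1:2], c("Cx", "Cx"))
  expect_true(is.na(calls$max_region[3]))

  # mean rest 0 limit convention: specific iff max log2 > 0
  m2 <- rbind(g1 = c(8, 1, 1), g2 = c(1, 1, 1))
  colnames(m2) <- c("Cx", "CB", "BS")
  calls2 <- rna_specificity(make_rna(m2))
  expect_true(calls2$specific[1])
  expect_false(calls2$specific[2])
})

test_that("RNA specificity is invariant to region column order", {
  set.seed(71)
  m <- matrix(rlnorm(50 * 5, 2, 1), 50, 5,
              dimnames = list(paste0("g", 1:50),
                              c("Cx", "CB", "BS", "HIP", "THA_HT")))
  a <- rna_specificity(make_rna(m))
  perm <- c(3, 5, 1, 2, 4)
  b <- rna_specificity(make_rna(m[, perm]))
  expect_equal(b$specific[match(a$gene_id, b$gene_id)], a$specific)
})

test_that("raising a specific gene's top nTPM never removes specificity", {
  set.seed(72)
  m <- matrix(rlnorm(30 * 5, 2, 1.5), 30, 5,
              dimnames = list(paste0("g", 1:30),
                              c("Cx", "CB", "BS", "HIP", "THA_HT")))
  a <- rna_specificity(make_rna(m))
  for (i in which(a$specific)) {
    m2 <- m
    m2[i, a$max_region[i]] <- m2[i, a$max_region[i]] * 10
    b <- rna_specificity(make_rna(m2))
    expect_true(b$specific[i])
  }
})

test_that("protein region calls map into the RNA vocabulary per the default map", {
  tab <- data.frame(protein_id = c("p1", "p2", "p3"),
                    max_region = c("PL", "VT", "CB"),
                    call = c(TRUE, TRUE, FALSE))
  mapped <- map_protein_regions_to_rna(tab)
  expect_equal(mapped$rna_region, c("Cx", NA, "CB"))
  expect_equal(mapped$mappable, c(TRUE, FALSE, TRUE))
  # identity map passes through
  idm <- setNames(region_codes(), region_codes())
  mapped2 <- map_protein_regions_to_rna(tab, idm)
  expect_equal(mapped2$rna_region, tab$max_region)
  # missing map entry for an encountered called region errors
  expect_error(map_protein_regions_to_rna(tab, c(PL = "Cx")), "VT")
})

test_that("concordance classes partition the protein universe", {
  p <- generator_params(n_proteins = 800, markers_per_region = 10,
                        rna_concordance = 1, rna_unmapped = 0.1, seed = 81)
  ds <- generate_proteome_dataset(p)
  lg <- log2_transform(to_ppm(ds$matrix))
  tab <- call_region_specific(lg, ds$annotations)
  rn <- generate_rna_table(ds$truth, p)
  rcalls <- rna_specificity(rn$rna)
  pcalls <- map_protein_regions_to_rna(tab)
  conc <- concordance_classify(pcalls, rcalls, rn$idmap)

  expect_equal(nrow(conc), nrow(tab))
  expect_false(any(is.na(conc$class)))
  expect_setequal(levels(conc$class),
                  c("both", "protein_only", "rna_only", "unmapped",
                    "background"))

  # every called marker in a mappable region with a mapped gene is "both",
  # and its regions agree
  rmap <- default_region_map()
  idx <- which(tab$call &
                 ds$truth$is_marker[match(tab$protein_id,
                                          ds$truth$protein_id)] &
                 !is.na(rmap[tab$max_region]) &
                 tab$protein_id %in% rn$idmap$protein_id)
  expect_gt(length(idx), 0)
  expect_true(all(conc$class[idx] == "both"))
  expect_true(all(conc$region_agreement[idx]))

  # proteins absent from the id map are unmapped regardless of calls
  off <- which(!tab$protein_id %in% rn$idmap$protein_id)
  expect_true(all(conc$class[off] == "unmapped"))
})

test_that("zero RNA concordance yields no 'both' class among markers", {
  p <- generator_params(n_proteins = 400, markers_per_region = 5,
                        rna_concordance = 0, seed = 82)
  ds <- generate_proteome_dataset(p)
  lg <- log2_transform(to_ppm(ds$matrix))
  tab <- call_region_specific(lg, ds$annotations)
  rn <- generate_rna_table(ds$truth, p)
  conc <- concordance_classify(map_protein_regions_to_rna(tab),
                               rna_specificity(rn$rna), rn$idmap)
  expect_false(any(conc$class == "both"))
  expect_error(
    concordance_classify(map_protein_regions_to_rna(tab),
                         rna_specificity(rn$rna),
                         rbind(rn$idmap, rn$idmap[1, ])),
    "duplicate")
})
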
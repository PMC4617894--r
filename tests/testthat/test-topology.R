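test_that("transporters are reactions moving a species between compartments", {
  toy <- make_toy_model()
  expect_setequal(classify_transporters(toy), "R_TA")

  # co-transport with a bystander metabolite still counts
  m <- contextcore:::build_model(
    mets_df(c("A_e", "A_c", "B_c")),
    list(SYM = list(mets = c(A_e = -1, A_c = 1, B_c = 1),
                    lb = 0, ub = 10)))
  expect_setequal(classify_transporters(m), "SYM")

  # conversion inside one compartment is not transport
  m2 <- contextcore:::build_model(
    mets_df(c("A_c", "B_c")),
    list(CONV = list(mets = c(A_c = -1, B_c = 1), lb = 0, ub = 10)))
  expect_length(classify_transporters(m2), 0)
})

test_that("transporter calls survive compartment relabeling", {
  toy <- make_toy_model()
  relabeled <- toy
  relabeled$metabolites$compartment <-
    ifelse(toy$metabolites$compartment == "e", "outside", "inside")
  expect_setequal(classify_transporters(relabeled), "R_TA")
})

test_that("flux directions come from FVA, not from bounds alone", {
  toy <- make_toy_model()
  d <- flux_directions(toy)
  expect_equal(unname(d["R1"]), "forward")
  expect_equal(unname(d["R4"]), "blocked")
  expect_equal(unname(d["R_EXA"]), "backward")   # uptake only

  cyc <- contextcore:::build_model(
    mets_df(c("X_c", "Y_c")),
    list(F1 = list(mets = c(X_c = -1, Y_c = 1), lb = -10, ub = 10),
         F2 = list(mets = c(Y_c = -1, X_c = 1), lb = -10, ub = 10)))
  expect_equal(unname(flux_directions(cyc)), c("both", "both"))
})

test_that("entry-point classes on TOY1 match the hand-traced truth", {
  toy <- make_toy_model()
  cons <- restrict_model(toy, fastcc(toy))
  ep <- find_entry_points(cons)
  rownames(ep) <- ep$reaction
  # R3 (PathY) consumes B made by R1 (PathX): pathway change
  expect_equal(ep["R3", "class"], "entry_pathway_change")
  # R1 (PathX) consumes A delivered by the transporter from the exchange
  # subsystem: pathway change
  expect_equal(ep["R1", "class"], "entry_pathway_change")
  # R2 (PathX) consumes B made by R1 (same subsystem): internal
  expect_equal(ep["R2", "class"], "internal")
  expect_equal(ep["R_TA", "class"], "transporter")

  # agreement with the independent graph-walk oracle
  dirs <- flux_directions(cons)
  trans <- classify_transporters(cons)
  for (r in ep$reaction)
    expect_equal(ep[r, "class"], oracle_entry_class(cons, r, dirs, trans),
                 info = r)
})

test_that("cofactor filtering drops couples and pure-cofactor reactions", {
  m <- make_cofactor_model()
  ep <- find_entry_points(m)
  rownames(ep) <- ep$reaction
  # HEX keeps glc (entry from Transport/Exchange) but its atp/adp couple is
  # dropped, so OxPhos never contaminates the call
  expect_equal(ep["HEX", "class"], "entry_pathway_change")
  # ADK consumes only cofactors: not considered
  expect_false(ep["ADK", "considered"])
  expect_equal(ep["ADK", "class"], "internal")

  # disabling filtering only adds entry calls, never removes them
  ep0 <- find_entry_points(m, cofactors = NULL)
  rownames(ep0) <- ep0$reaction
  entry_classes <- c("entry_pathway_change", "entry_compartment_change")
  was_entry <- ep$reaction[ep$class %in% entry_classes]
  expect_true(all(ep0[was_entry, "class"] %in% entry_classes))
  expect_gte(sum(ep0$class %in% entry_classes),
             sum(ep$class %in% entry_classes))
})

test_that("adding a pure-cofactor reaction leaves other calls unchanged", {
  m <- make_cofactor_model()
  before <- find_entry_points(m)
  # append another adenylate-balance reaction (pure cofactors)
  rx <- m$reactions
  rx <- rbind(rx, data.frame(id = "ADK2", lb = 0, ub = 10, gpr = "AK2",
                             subsystem = "NucMet"))
  S2 <- cbind(m$S, ADK2 = 0)
  S2[c("adp_c", "atp_c", "amp_c"), "ADK2"] <- c(2, -1, -1)
  m2 <- metabolic_model(m$metabolites, rx, S2, id = m$id)
  after <- find_entry_points(m2)
  shared <- intersect(before$reaction, after$reaction)
  expect_equal(after$class[match(shared, after$reaction)],
               before$class[match(shared, before$reaction)])
})

test_that("compartment-change entries are distinguished from pathway changes", {
  # same subsystem on both sides of a membrane: compartment change
  m <- contextcore:::build_model(
    mets_df(c("A_m", "A_c", "B_c", "P_m")),
    list(SRC = list(mets = c(P_m = 1), lb = 0, ub = 10, gpr = "GS",
                    subsystem = "PathX"),
         MK  = list(mets = c(P_m = -1, A_m = 1), lb = 0, ub = 10, gpr = "GM",
                    subsystem = "PathX"),
         TAM = list(mets = c(A_m = -1, A_c = 1), lb = 0, ub = 10, gpr = "GT",
                    subsystem = "Transport"),
         USE = list(mets = c(A_c = -1, B_c = 1), lb = 0, ub = 10, gpr = "GU",
                    subsystem = "PathX"),
         DM  = list(mets = c(B_c = -1), lb = 0, ub = 10,
                    subsystem = "Exchange")))
  ep <- find_entry_points(m)
  rownames(ep) <- ep$reaction
  expect_equal(ep["USE", "class"], "entry_compartment_change")
})

test_that("positional enrichment builds the documented count tables", {
  ann <- data.frame(
    reaction = sprintf("r%02d", 1:20),
    class = c(rep("transporter", 5), rep("entry_pathway_change", 4),
              rep("internal", 11)),
    direction = "forward", considered = TRUE, stringsAsFactors = FALSE)
  hrl <- sprintf("r%02d", 1:5)   # all HRL reactions are transporters

  tr <- positional_enrichment(ann, hrl, mode = "transporters")
  expect_equal(tr[c("N", "K", "n", "k")], list(N = 20, K = 5, n = 5, k = 5))
  expect_lt(tr$p, 0.05)
  expect_equal(tr$p, oracle_hyper_tail(20, 5, 5, 5), tolerance = 1e-12)

  none <- positional_enrichment(ann, character(0), mode = "transporters")
  expect_equal(none$k, 0)
  expect_equal(none$p, 1)

  ep <- positional_enrichment(ann, c("r06", "r10"),
                              mode = "entry_points_excluding_transporters")
  expect_equal(ep$N, 15)          # transporters excluded from the population
  expect_equal(ep$K, 4)
  expect_equal(ep$n, 2)
  expect_equal(ep$k, 1)

  comb <- positional_enrichment(ann, c("r01", "r06", "r10"),
                                mode = "combined")
  expect_equal(comb$K, 9)
  expect_equal(comb$k, 2)
})

test_that("edge-list export enumerates all incidences", {
  toy <- make_toy_model()
  edges <- export_edge_list(toy)
  expect_equal(nrow(edges), sum(toy$S != 0))
  expect_setequal(unique(edges$role), c("substrate", "product"))
})
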
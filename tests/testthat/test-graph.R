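# hand-built correlation tables exercise the window rules without simulation
fake_cc <- function(rows) {
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(a = r[[1]], b = r[[2]], c0 = as.numeric(r[[3]]),
               cmax = as.numeric(r[[4]]), lag_bins = as.integer(r[[5]]),
               delay_ms = as.integer(r[[5]]) * 5, p = as.numeric(r[[6]]),
               significant = as.numeric(r[[6]]) <= 0.01,
               undefined = length(r) >= 7 && isTRUE(r[[7]]),
               stringsAsFactors = FALSE)
  }))
  attr(df, "bin_ms") <- 5
  attr(df, "max_lag_bins") <- 5
  attr(df, "alpha") <- 0.01
  class(df) <- c("correlation_result", "data.frame")
  df
}

lay <- build_layout()

test_that("window rules split short-term and delayed edges", {
  cc <- fake_cc(list(
    list("33", "35", .6, .6, 0, 1e-3),          # central-bin max -> short term
    list("24", "34", .2, .5, 2, 1e-3),          # +2 bins -> delayed 24 -> 34
    list("44", "24", .2, .4, -3, 1e-3),         # -3 bins -> delayed 24 -> 44
    list("33", "46", .1, .2, 1, 0.5),           # not significant
    list("64", "74", .1, .2, 0, 0.5),           # not significant
    list("82", "83", 0, 0, NA, NA, TRUE)        # undefined pair
  ))
  gs <- short_term_graph(cc, lay)
  gd <- delayed_graph(cc, lay)
  expect_equal(nrow(gs), 1L)
  expect_equal(gs$a, "33"); expect_equal(gs$b, "35")
  expect_equal(gs$edge_class, "same_column")
  expect_equal(nrow(gd), 2L)
  expect_equal(gd$from, c("24", "24"))
  expect_equal(gd$to, c("34", "44"))
  expect_equal(gd$delay_ms, c(10, 15))
  expect_true(all(gd$edge_class == "soma_neurite"))
  # window partition: no pair appears in both graphs
  expect_length(intersect(paste(gs$a, gs$b),
                          c(paste(gd$from, gd$to), paste(gd$to, gd$from))), 0)
})

test_that("delayed edges respect the 5-25 ms window by construction", {
  cc <- fake_cc(list(list("33", "35", .2, .6, 1, 1e-3),
                     list("34", "36", .2, .6, 5, 1e-3)))
  gd <- delayed_graph(cc, lay)
  expect_true(all(gd$delay_ms >= 5 & gd$delay_ms <= 25))
})

test_that("classify_edges counts classes, spans and compartment density", {
  cc <- fake_cc(list(
    list("23", "73", .5, .5, 0, 1e-3),   # somatic col2 -> long col7, row 3
    list("33", "35", .5, .5, 0, 1e-3),
    list("44", "45", .5, .5, 0, 1e-3)
  ))
  gs <- short_term_graph(cc, lay)
  cl <- classify_edges(gs, lay)
  expect_equal(unname(cl$class_counts["soma_neurite"]), 1L)
  expect_equal(unname(cl$class_counts["same_column"]), 2L)
  expect_equal(gs$span_pitches[gs$a == "23"], 5L)
  pc <- cl$per_compartment
  expect_equal(sum(pc$n_endpoints), 2L * nrow(gs))
  expect_equal(pc$edges_per_electrode[pc$compartment == "empty_chamber"], 0)
  # closed world: edges within one somatic chamber are all soma_neurite
  cc2 <- fake_cc(list(list("12", "24", .5, .5, 0, 1e-3)))
  cl2 <- classify_edges(short_term_graph(cc2, lay), lay)
  expect_equal(unname(cl2$class_counts["soma_neurite"]), 1L)
  expect_equal(sum(cl2$class_counts), 1L)
})

test_that("node roles follow the in/out-degree definitions", {
  cc <- fake_cc(list(
    list("24", "34", .2, .5, 2, 1e-3),   # 24 -> 34
    list("24", "44", .2, .5, 3, 1e-3),   # 24 -> 44
    list("44", "12", .2, .5, 2, 1e-3),   # 44 -> 12 (somatic afferent)
    list("25", "26", .2, .5, 1, 1e-3),   # 25 -> 26 soma -> soma
    list("26", "36", .2, .5, 1, 1e-3)    # 26 -> 36: 26 becomes mixed
  ))
  gd <- delayed_graph(cc, lay)
  roles <- node_roles(gd, lay)
  role_of <- function(id) roles$role[roles$electrode == id]
  expect_equal(role_of("24"), "efferent")
  expect_equal(role_of("12"), "afferent")
  expect_equal(role_of("26"), "mixed")
  expect_equal(role_of("28"), "isolated")
  # non-somatic electrodes carry degrees but no role
  expect_true(is.na(role_of("44")))
  expect_equal(roles$in_degree[roles$electrode == "44"], 1L)
  expect_equal(roles$out_degree[roles$electrode == "44"], 1L)
  # degree conservation
  expect_equal(sum(roles$out_degree), nrow(gd))
  expect_equal(sum(roles$in_degree), nrow(gd))
})

test_that("time reversal flips delayed-edge orientation", {
  set.seed(31)
  l2 <- build_layout(config_2x2())
  base <- sort(runif(150, 0.2, 9.7))
  dur <- 10
  tr <- make_trains(list("11" = base, "21" = sort(base + 0.012)), dur)
  rev <- make_trains(lapply(tr$trains, function(t) sort(dur - t)), dur)
  cc_f <- correlate_pairs(tr, n_surrogates = 199, seed = 4)
  cc_r <- correlate_pairs(rev, n_surrogates = 199, seed = 4)
  gd_f <- delayed_graph(cc_f, l2)
  gd_r <- delayed_graph(cc_r, l2)
  skip_if(nrow(gd_f) == 0, "no forward edge recovered")
  expect_equal(nrow(gd_r), nrow(gd_f))
  expect_equal(gd_r$from, gd_f$to)
  expect_equal(gd_r$to, gd_f$from)
})

test_that("graphs export to valid GraphML and round-trip through igraph", {
  cc <- fake_cc(list(list("24", "34", .2, .5, 2, 1e-3),
                     list("24", "44", .2, .5, 3, 1e-3)))
  gd <- delayed_graph(cc, lay)
  path <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(gd, lay, path)
  doc <- xml2::read_xml(path)
  expect_equal(xml2::xml_name(doc), "graphml")
  g <- igraph::read_graph(path, format = "graphml")
  expect_true(igraph::is_directed(g))
  expect_equal(igraph::gsize(g), 2)
  expect_equal(igraph::vcount(g), 60)
  ge <- igraph::as_data_frame(g)
  expect_setequal(ge$to, c("34", "44"))
  expect_setequal(ge$delay_ms, c(10, 15))
})
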
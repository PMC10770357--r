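lex <- make_test_lexicon()

test_that("a fresh session is empty and sessions are independent", {
  s1 <- new_session("s1")
  s2 <- new_session("s2")
  expect_true(is.na(s1$gene) && is.na(s1$cancer_type) && is.na(s1$data_type))
  s1 <- apply_attribute(s1, "GENE", "TP53")
  expect_true(is.na(s2$gene))
  # reset of a filled state equals a fresh session
  reset <- new_session("s1")
  expect_equal(unclass(reset), unclass(new_session("s1")))
})

test_that("attribute updates are order-independent and retain context", {
  updates <- list(c("GENE", "TP53"), c("CANCER_TYPE", "breast cancer"),
                  c("DATA_TYPE", "mutations"))
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  finals <- lapply(perms, function(p) {
    s <- new_session()
    for (i in p) s <- apply_attribute(s, updates[[i]][1], updates[[i]][2])
    s
  })
  for (s in finals[-1]) expect_equal(unclass(s), unclass(finals[[1]]))
  # switching one value leaves the other slots intact
  s <- finals[[1]]
  s2 <- apply_attribute(s, "GENE", "PIK3CA")
  expect_equal(s2$gene, "PIK3CA")
  expect_equal(s2$cancer_type, s$cancer_type)
  expect_equal(s2$data_type, s$data_type)
  expect_error(apply_attribute(s, "PROTEIN", "x"), "attribute_type")
})

test_that("response dispatch is total over all fill patterns and intents", {
  values <- list(GENE = "TP53", CANCER_TYPE = "breast cancer",
                 DATA_TYPE = "mutations")
  intents <- list(intent("NAVIGATE"), intent("RESET"), intent("HELP"),
                  intent("COMPARE", list(attribute_type = "GENE",
                                         value_b = "MYC")),
                  intent("SPLIT_BY", list(partition_gene = "MYC")))
  for (mask in 0:7) {
    s <- new_session()
    fill <- c(bitwAnd(mask, 1) > 0, bitwAnd(mask, 2) > 0, bitwAnd(mask, 4) > 0)
    types <- c("GENE", "CANCER_TYPE", "DATA_TYPE")[fill]
    for (t in types) s <- apply_attribute(s, t, values[[t]])
    for (it in intents) {
      resp <- resolve_response(s, it)
      expect_s3_class(resp, "response_spec")
      expect_true(resp$response_class %in%
                    c("PROMPT_MISSING", "OVERVIEW_LIST", "GENE_SUMMARY",
                      "COMPARE_VIEW", "SPLITBY_VIEW", "ERROR_TEXT"),
                  label = sprintf("mask=%d kind=%s", mask, it$kind))
    }
  }
})

test_that("navigate dispatch matches the fill pattern", {
  s <- new_session()
  expect_equal(resolve_response(s)$response_class, "PROMPT_MISSING")
  # prompting order asks for data type first
  expect_equal(resolve_response(s)$payload$ask, "DATA_TYPE")
  s <- apply_attribute(s, "DATA_TYPE", "mutations")
  expect_equal(resolve_response(s)$payload$ask, "CANCER_TYPE")
  s <- apply_attribute(s, "CANCER_TYPE", "breast cancer")
  expect_equal(resolve_response(s)$response_class, "OVERVIEW_LIST")
  s <- apply_attribute(s, "GENE", "TP53")
  resp <- resolve_response(s)
  expect_equal(resp$response_class, "GENE_SUMMARY")
  expect_equal(resp$payload$gene, "TP53")
})

test_that("split-by demands a quantitative data type", {
  s <- new_session()
  s <- apply_attribute(s, "GENE", "PIK3CA")
  s <- apply_attribute(s, "CANCER_TYPE", "breast cancer")
  s <- apply_attribute(s, "DATA_TYPE", "mutations")
  resp <- resolve_response(s, intent("SPLIT_BY", list(partition_gene = "TP53")))
  expect_equal(resp$response_class, "ERROR_TEXT")
  expect_match(resp$speech_text, "quantitative")
  s <- apply_attribute(s, "DATA_TYPE", "gene expression")
  resp <- resolve_response(s, intent("SPLIT_BY", list(partition_gene = "TP53")))
  expect_equal(resp$response_class, "SPLITBY_VIEW")
  expect_equal(resp$payload$partition_gene, "TP53")
})

test_that("intent parsing recognizes trigger phrases", {
  s <- new_session()
  s <- apply_attribute(s, "GENE", "PIK3CA")
  unresolved <- match_result()
  it <- parse_intent(unresolved, s, "split by tp53", lex)
  expect_equal(it$kind, "SPLIT_BY")
  expect_equal(it$payload$partition_gene, "TP53")
  it <- parse_intent(unresolved, s, "compare it with mutations", lex)
  expect_equal(it$kind, "COMPARE")
  expect_equal(it$payload$attribute_type, "DATA_TYPE")
  expect_equal(it$payload$value_b, "mutations")
  expect_equal(parse_intent(unresolved, s, "reset", lex)$kind, "RESET")
  expect_equal(parse_intent(unresolved, s, "zzz", lex)$kind, "HELP")
  resolved <- match_result("TP53", "GENE", "EXACT", 1)
  it <- parse_intent(resolved, s, "tp53", lex)
  expect_equal(it$kind, "NAVIGATE")
  expect_equal(it$payload$value, "TP53")
})

test_that("sessions survive a JSON round trip exactly", {
  s <- new_session("abc")
  s <- apply_attribute(s, "GENE", "TP53")
  path <- withr::local_tempfile(fileext = ".json")
  save_session(s, path)
  s2 <- load_session(path)
  expect_equal(unclass(s2), unclass(s))
  # including empty slots
  save_session(new_session("x"), path)
  expect_equal(unclass(load_session(path)), unclass(new_session("x")))
})
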
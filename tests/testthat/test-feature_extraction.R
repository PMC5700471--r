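test_that("word shapes follow the X/x/d mapping with collapsed variant", {
  expect_equal(unname(word_shape("Kidney")), c("Xxxxxx", "Xx"))
  expect_equal(unname(word_shape("HP_0000077")), c("XX_ddddddd", "X_d"))
  expect_equal(unname(word_shape("x")), c("x", "x"))
})

test_that("token features contain exactly the enabled families", {
  txt <- "renal dysplasia"
  tk <- tokenize_and_tag(data.frame(start = 0L, end = nchar(txt)), txt)

  # golden set for "dysplasia", morphological + linguistic only,
  # derived by hand from the stated affix lengths and shape mapping
  cfg <- feature_config(orthographic = FALSE, context = FALSE,
                        lexical = FALSE, other = FALSE)
  got <- token_features(tk, 2L, cfg)
  expect_setequal(got, c(
    "w=dysplasia", "lemma=dysplasia", paste0("pos=", tk$pos[2]),
    "pre2=dy", "pre3=dys",
    "suf1=a", "suf2=ia", "suf3=sia", "suf4=asia",
    "shape=xxxxxxxxx", "shapec=x",
    paste0("bg=", c("dy", "ys", "sp", "pl", "la", "as", "si", "ia"))))

  # baseline: current token text only
  expect_equal(token_features(tk, 2L, baseline_config()), "w=dysplasia")

  # boundary sentinels at sentence start
  ctx <- feature_config(linguistic = FALSE, orthographic = FALSE,
                        morphological = FALSE, lexical = FALSE, other = FALSE)
  f1 <- token_features(tk, 1L, ctx)
  expect_true("lemma[-1]=_BOS_" %in% f1)
  expect_true("lemma[-2]=_BOS_" %in% f1)
  expect_true("pos[-4]=_BOS_" %in% f1)
  expect_true("lemma[1]=dysplasia" %in% f1)
  expect_true("lemma[2]=_EOS_" %in% f1)

  # orthographic symbol presence flags
  orto <- feature_config(linguistic = FALSE, morphological = FALSE,
                         context = FALSE, lexical = FALSE, other = FALSE)
  tk2 <- tokenize_and_tag(data.frame(start = 0L, end = 3L), "p53")
  f2 <- token_features(tk2, 1L, orto)
  expect_true(all(c("case=mixed", "sym_digit") %in% f2))
})

test_that("feature extraction is position-local", {
  mk <- function(txt) tokenize_and_tag(data.frame(start = 0L,
                                                  end = nchar(txt)), txt)
  a <- mk("one two three four five six seven eight nine ten")
  b <- mk("one two three four five six seven eight nine ZZZ")
  cfg <- feature_config()  # widest window is 4
  for (i in 1:5) {          # tokens whose windows exclude position 10
    expect_equal(token_features(a, i, cfg), token_features(b, i, cfg))
  }
  expect_false(identical(token_features(a, 10L, cfg),
                         token_features(b, 10L, cfg)))
})

test_that("BIO encoding and decoding are mutually inverse", {
  txt <- "We saw renal dysplasia there."
  tk <- preprocess_document(txt)[[1]]$tokens
  s <- as.integer(regexpr("renal dysplasia", txt)) - 1L
  ann <- data.frame(doc_id = "d", start = s, end = s + 15L,
                    hpo_id = "HP_0000110", surface = "renal dysplasia")
  lab <- encode_bio(tk, ann)
  expect_equal(as.character(lab), c("O", "O", "B", "I", "O", "O"))
  expect_equal(as.character(encode_bio(tk, NULL)), rep("O", 6))

  dec <- decode_bio(tk, lab, txt)
  expect_equal(dec$start, s)
  expect_equal(dec$end, s + 15L)
  expect_equal(dec$surface, "renal dysplasia")

  # stray I at sentence start repaired to B
  rep_lab <- c("I", "O", "O", "O", "O", "O")
  dec2 <- decode_bio(tk, rep_lab, txt)
  expect_equal(attr(dec2, "repaired"), 1L)
  expect_equal(dec2$surface, "We")

  # all-O decodes to nothing
  expect_equal(nrow(decode_bio(tk, rep("O", 6), txt)), 0L)
})

test_that("encode/decode round-trips across the generated corpus", {
  fx <- fx_default()
  for (i in seq_len(nrow(fx$corpus$documents))) {
    id <- fx$corpus$documents$doc_id[i]
    text <- fx$corpus$documents$text[i]
    ann <- fx$corpus$annotations[fx$corpus$annotations$doc_id == id, ]
    recovered <- list()
    for (sent in preprocess_document(text, id)) {
      lab <- encode_bio(sent$tokens, ann)
      d <- decode_bio(sent$tokens, lab, text)
      if (nrow(d)) recovered[[length(recovered) + 1L]] <- d
    }
    recovered <- do.call(rbind, recovered)
    # every non-nested gold span is recovered exactly; nested inner spans
    # are absorbed by the longest-span-wins projection
    keep <- rep(TRUE, nrow(ann))
    for (r in seq_len(nrow(ann))) {
      keep[r] <- !any(ann$start <= ann$start[r] & ann$end >= ann$end[r] &
                        (ann$end - ann$start) > (ann$end[r] - ann$start[r]))
    }
    outer_ann <- ann[keep, ]
    expect_setequal(paste(recovered$start, recovered$end),
                    paste(outer_ann$start, outer_ann$end))
  }
})
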
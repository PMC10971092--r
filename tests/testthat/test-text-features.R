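ext <- function(f) system.file("extdata", f, package = "iedina")

test_that("preprocessing strips symbols and digits, splits sentences", {
  pp <- preprocess_stem("What is 3 + 4?")
  expect_equal(pp$tokens, c("what", "is"))
  expect_equal(length(pp$sentences), 1)
  pp2 <- preprocess_stem("The cat sat.")
  expect_equal(pp2$tokens, c("the", "cat", "sat"))
  pp3 <- preprocess_stem("Count the dots. Then write the sum.")
  expect_equal(length(pp3$sentences), 2)
  empty <- preprocess_stem("3 + 4 = 7")
  expect_true(attr(empty, "empty"))
  expect_error(preprocess_stem(""), "non-empty")
})

test_that("raw-token features count words and long tokens", {
  tf <- token_features(c("people", "wear", "glasses"))
  expect_equal(tf$word_token, 3)
  expect_equal(tf$prop_six_letters, 2 / 3)
  expect_equal(token_features(c("a", "cat"))$prop_six_letters, 0)
  expect_equal(token_features(c("elephant", "giraffe"))$prop_six_letters, 1)
  none <- token_features(character(0))
  expect_true(is.na(none$prop_six_letters) && attr(none, "empty"))
})

test_that("word-list features count membership and popularity", {
  fam <- c("cat", "sat", "the")
  freq <- c(cat = 10, sat = 2)
  fun <- c("the", "a")
  wf <- wordlist_features(c("cat", "sat"), fam, freq, fun)
  expect_equal(wf$n_unfamiliar, 0)
  expect_equal(wf$popularity, 6)        # mean of 10 and 2
  expect_equal(wf$n_function_words, 0)
  wf2 <- wordlist_features(c("cat", "zyzzyva", "the"), fam, freq, fun)
  expect_equal(wf2$n_unfamiliar, 1)
  expect_equal(wf2$n_function_words, 1)
  # summed-popularity switch
  expect_equal(wordlist_features(c("cat", "sat"), fam, freq, fun,
                                 popularity_mode = "sum")$popularity, 12)
  expect_error(read_wordlist("/nonexistent/words.txt"), "not found")
})

test_that("POS features count adjectives and adverbs via the tag map", {
  tagger <- lookup_tagger(c(quickly = "RB", red = "JJ", green = "JJ"))
  pf <- pos_features(c("run", "quickly"), tagger)
  expect_equal(pf$n_adverbs, 1)
  expect_equal(pf$n_adjectives, 0)
  pf2 <- pos_features(c("red", "green", "box"), tagger)
  expect_equal(pf2$n_adjectives, 2)
  # unmapped tags count in no class; tagger failure flags the item
  pf3 <- pos_features("box", tagger)
  expect_equal(pf3$n_adjectives + pf3$n_adverbs, 0)
  bad <- pos_features("x", function(t) stop("boom"))
  expect_true(attr(bad, "failed") && is.na(bad$n_adjectives))
})

test_that("extraction is a pure function of stems and resources", {
  stems <- utils::read.csv(ext("synthetic_item_stems.csv"),
                           stringsAsFactors = FALSE)
  fam <- read_wordlist(ext("synthetic_familiar_words.txt"))
  freq <- read_wordlist(ext("synthetic_corpus_frequencies.tsv"),
                        frequency = TRUE)
  fun <- read_wordlist(ext("synthetic_function_words.txt"))
  tm <- utils::read.csv(ext("synthetic_tag_map.csv"),
                        stringsAsFactors = FALSE)
  tagger <- lookup_tagger(stats::setNames(tm$tag, tm$token))
  z1 <- extract_item_features(stems, fam, freq, fun, tagger)
  z2 <- extract_item_features(stems, fam, freq, fun, tagger)
  expect_identical(z1, z2)
  expect_equal(dim(z1), c(10, 8))
  expect_true(all(is.finite(z1)))
  # metadata columns pass through untouched
  expect_equal(unname(z1[, "story"]), stems$story)
  expect_equal(unname(z1[, "item_type"]), stems$item_type)
  # spot-check one stem by hand: "Draw a long line under the triangle."
  expect_equal(unname(z1["item2", "word_token"]), 7)
  expect_equal(unname(z1["item2", "n_adjectives"]), 1)   # "long"
  expect_equal(unname(z1["item2", "prop_six_letters"]), 1 / 7) # "triangle"
})

test_that("screening retains weakly correlated features and reports VIF", {
  set.seed(19)
  a <- rnorm(60); b <- rnorm(60); c <- rnorm(60)
  # duplicate column dropped
  z <- cbind(a = a, a2 = a, b = b)
  rep <- screen_features(z)
  expect_equal(rep$status$retained, c(TRUE, FALSE, TRUE))
  expect_match(rep$status$reason[2], "rho")
  # orthogonal columns all kept with VIF ~ 1
  zo <- cbind(a = a, b = b, c = c)
  ro <- screen_features(zo)
  expect_true(all(ro$status$retained))
  expect_true(all(ro$vif < 1.3))
  # greedy order: the later member of a correlated pair loses
  x1 <- rnorm(200)
  x2 <- 0.9 * x1 + sqrt(1 - 0.81) * rnorm(200)
  x3 <- rnorm(200)
  zg <- cbind(f1 = x1, f2 = x2, f3 = x3)
  rg <- screen_features(zg)
  expect_equal(rg$status$retained, c(TRUE, FALSE, TRUE))
  # zero-variance column dropped with reason
  zz <- cbind(k = rep(1, 60), a = a)
  rz <- screen_features(zz)
  expect_equal(rz$status$reason[1], "zero variance")
  # the report satisfies its own thresholds
  zr <- matrix(rnorm(600), 100, 6)
  rr <- screen_features(zr)
  kept <- rr$features
  if (ncol(kept) > 1) {
    cors <- stats::cor(kept); diag(cors) <- 0
    expect_lt(max(abs(cors)), 0.3)
  }
  expect_true(all(rr$vif < 5))
})
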
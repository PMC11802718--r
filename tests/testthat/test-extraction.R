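test_that("prompts inline the category and carry the escape instruction", {
  p <- build_prompt("alcohol", "severe etoh use d/o")
  expect_match(p, "^Extract the reference to alcohol use disorder diagnosis")
  expect_match(p, "unanswerable", fixed = TRUE)
  expect_match(p, "Note: severe etoh use d/o$")
  expect_match(build_prompt("cannabis", "any text"), "cannabis use disorder",
               fixed = TRUE)
  expect_match(build_prompt("alcohol", ""), "Note: $")
  expect_error(build_prompt("alcohol", "x", template = "no placeholders"),
               "placeholder")
  expect_error(build_prompt("alcohol", "x", template = "{note} {note}"),
               "placeholder")
  expect_error(build_prompt("alcohol", "x",
                            template = "find {category} here {note}"),
               "sentinel|escape")
  expect_error(build_prompt("not_a_category", "x"), "unknown")
})

test_that("the sentinel check is case-insensitive substring containment", {
  expect_true(is_unanswerable("unanswerable"))
  expect_false(is_unanswerable("severe etoh use d/o"))
  expect_true(is_unanswerable("the answer is Unanswerable."))
  expect_true(is_unanswerable(NA_character_))
})

test_that("extraction yields one candidate per chunk, in chunk order", {
  notes <- tiny_notes()
  gold <- tiny_gold()
  backend <- backend_oracle(gold)

  pos <- run_extraction(notes[1, ], "alcohol", backend)
  expect_identical(nrow(pos), 1L)
  expect_identical(pos$text, "severe etoh use d/o")

  neg <- run_extraction(notes[2, ], "alcohol", backend)
  expect_identical(neg$text, sud_sentinel())

  long_note <- list(note_id = "n3",
                    text = paste(paste0("w", 1:585), collapse = " "))
  cands <- run_extraction(long_note, "alcohol", backend)
  expect_identical(nrow(cands), 2L)
  expect_identical(cands$chunk_index, 0:1)

  empty <- list(note_id = "n4", text = "")
  expect_warning(out <- run_extraction(empty, "alcohol", backend), "empty")
  expect_identical(nrow(out), 0L)
})

test_that("backend failures degrade to per-chunk sentinels", {
  failing <- new_backend("boom", function(input, cfg, ctx) stop("backend down"))
  expect_warning(
    out <- run_extraction(tiny_notes()[1, ], "alcohol", failing),
    "backend down")
  expect_identical(out$text, sud_sentinel())
})

test_that("runs are deterministic and backends are substitutable", {
  notes <- tiny_notes()
  gold <- tiny_gold()
  for (bk in list(backend_oracle(gold), backend_noisy(gold),
                  backend_hallucinating(gold, rate = 0.5))) {
    a <- lapply(seq_len(nrow(notes)), function(i) {
      run_extraction(notes[i, ], "alcohol", bk)
    })
    b <- lapply(seq_len(nrow(notes)), function(i) {
      run_extraction(notes[i, ], "alcohol", bk)
    })
    expect_identical(a, b)
  }
})

test_that("the noisy mock decorates oracle answers without touching sentinels", {
  out <- run_extraction(tiny_notes()[1, ], "alcohol",
                        backend_noisy(tiny_gold()))
  expect_match(out$text, "severe etoh use d/o", fixed = TRUE)
  expect_false(identical(out$text, "severe etoh use d/o"))
  neg <- run_extraction(tiny_notes()[2, ], "alcohol",
                        backend_noisy(tiny_gold()))
  expect_identical(neg$text, sud_sentinel())
})

test_that("generated answers respect the max_new_tokens cap", {
  gold <- tibble::tibble(note_id = "n1", category = "alcohol",
                         span_text = paste(rep("alcohol use disorder", 60),
                                           collapse = " "))
  note <- list(note_id = "n1",
               text = paste("dx:", gold$span_text))
  out <- run_extraction(note, "alcohol", backend_oracle(gold),
                        generation_config(max_new_tokens = 100L))
  expect_lte(max(vapply(out$text, count_tokens, integer(1))), 100L)
})
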
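# Repeat template geometry: position naming, spans, round-trips.

test_that("template position naming matches hand enumeration", {
  loops <- c(l_da = 6, l_ab = 4, l_bc = 4)
  expect_equal(templatePositionOf(0, loops),
               list(element = "Sd", index = 1L))
  expect_equal(templatePositionOf(23, c(l_da = 0, l_ab = 0, l_bc = 0)),
               list(element = "Sc", index = 6L))
  # 6 Sd + 4 Lda precede offset 10 when l_da = 4
  expect_equal(templatePositionOf(10, c(l_da = 4, l_ab = 4, l_bc = 4)),
               list(element = "Sa", index = 1L))
  expect_error(templatePositionOf(38, loops), "outside")
  expect_error(templatePositionOf(-1, loops), "outside")
})

test_that("position naming round-trips through its inverse", {
  for (seed in 1:5) {
    loops <- withr::with_seed(seed, c(l_da = sample(1:15, 1),
                                      l_ab = sample(1:15, 1),
                                      l_bc = sample(1:15, 1)))
    total <- 24 + sum(loops)
    for (off in seq_len(total) - 1L) {
      p <- templatePositionOf(off, loops)
      expect_identical(unname(templateOffsetOf(p$element, p$index, loops)),
                       off)
    }
  }
})

test_that("candidate spans follow 24 + loop lengths", {
  expect_equal(candidateSpan(0, c(l_da = 6, l_ab = 4, l_bc = 4)), c(0, 38))
  expect_equal(candidateSpan(5, c(l_da = 0, l_ab = 0, l_bc = 0)), c(5, 29))
  expect_equal(candidateSpan(0, c(l_da = 15, l_ab = 15, l_bc = 15)),
               c(0, 69))
  expect_error(candidateSpan(-1, c(l_da = 1, l_ab = 1, l_bc = 1)),
               "negative")
})

test_that("the scored-position set has exactly 31 members", {
  expect_length(scoredPositions(), 31L)
  # 24 strand + 7 loop positions, and scored offsets agree with the
  # template naming for any loop lengths
  for (seed in 1:5) {
    loops <- withr::with_seed(seed, c(l_da = sample(3:15, 1),
                                      l_ab = sample(4:15, 1),
                                      l_bc = sample(3:15, 1)))
    off <- propellerscan:::scoredOffsets(loops)
    expect_length(off, 31L)
    expect_false(anyNA(off))   # long enough loops hold every scored slot
    for (k in names(off)) {
      p <- templatePositionOf(off[[k]], loops)
      expect_identical(paste0(p$element, p$index), k)
    }
  }
})

test_that("short loops lose exactly their missing scored positions", {
  off <- propellerscan:::scoredOffsets(c(l_da = 2, l_ab = 2, l_bc = 2))
  expect_true(is.na(off[["Lda3"]]))
  expect_false(is.na(off[["Lda2"]]))
  expect_true(all(is.na(off[c("Lab3", "Lab4", "Lbc3")])))
  expect_false(anyNA(off[c("Lab1", "Lab2")]))
})
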
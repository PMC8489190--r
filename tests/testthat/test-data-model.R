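test_that("datasets are read verbatim with roles applied and boundaries handled", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,x", "2,y"), f)
  d <- read_dataset(f, roles = c(a = "quasi_identifying"))
  expect_s3_class(d, "anon_dataset")
  expect_equal(nrow(d), 2L)
  expect_identical(d$a, c("1", "2"))
  expect_identical(unname(attribute_roles(d)), c("quasi_identifying", "insensitive"))
  expect_identical(quasi_identifiers(d), "a")

  # header-only file is a valid empty dataset
  writeLines("a,b", f)
  expect_equal(nrow(read_dataset(f)), 0L)

  # ragged rows are an error naming the offending row
  writeLines(c("a,b", "1,x", "2,y,z"), f)
  expect_error(read_dataset(f), "row 2")

  # duplicate header names and unknown-attribute roles are errors
  writeLines(c("a,a", "1,2"), f)
  expect_error(read_dataset(f), "duplicate")
  writeLines(c("a,b", "1,x"), f)
  expect_error(read_dataset(f, roles = c(zzz = "insensitive")), "zzz")
})

test_that("dataset writing round-trips bit-exactly", {
  f <- withr::local_tempfile(fileext = ".csv")
  toy <- toy8()
  write_dataset(toy$data, f)
  back <- read_dataset(f, roles = attr(toy$data, "roles"))
  expect_identical(as.data.frame(back), as.data.frame(toy$data))
})

test_that("hierarchy files parse, round-trip, and enforce functional mappings", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("male;*", "female;*"), f)
  h <- read_hierarchy(f)
  expect_equal(hierarchy_height(h), 1L)
  expect_setequal(hierarchy_leaves(h), c("male", "female"))
  expect_identical(unique(h[, 2]), "*")

  # single column = identity hierarchy, height 0
  writeLines(c("a", "b", "c"), f)
  expect_equal(hierarchy_height(read_hierarchy(f)), 0L)

  # equal leaves mapping to different parents violate functionality
  writeLines(c("34;30-39", "34;40-49"), f)
  expect_error(read_hierarchy(f), "map to multiple|duplicate")

  writeLines(c("a;x;*", "b;x"), f)
  expect_error(read_hierarchy(f), "ragged")

  g <- withr::local_tempfile()
  toy <- toy8()
  write_hierarchy(toy$hierarchies$age, g)
  expect_identical(unclass(read_hierarchy(g, attribute = "age")),
                   unclass(toy$hierarchies$age))
})

test_that("validate_hierarchy reports violations instead of raising", {
  sex <- hierarchy(cbind(c("male", "female"), c("*", "*")), "sex")
  expect_length(validate_hierarchy(sex, c("male", "female")), 0L)
  rep1 <- validate_hierarchy(sex, c("male", "unknown"))
  expect_match(rep1, "unknown", all = FALSE)
  dup <- hierarchy(cbind(c("a", "a"), c("*", "*")), "x")
  expect_match(validate_hierarchy(dup), "duplicate leaf", all = FALSE)
})

test_that("hierarchy composition is consistent level over level", {
  # applying level l then the l -> l+1 mapping equals applying l+1 directly
  for (seed in 1:10) {
    syn <- generate_dataset(5, list(list(domain_size = sample(3:16, 1),
                                         branching_factor = sample(2:3, 1))),
                            seed = seed)
    tab <- unclass(syn$hierarchies[[1]])
    expect_length(validate_hierarchy(syn$hierarchies[[1]]), 0L)
    for (l in seq_len(ncol(tab) - 1L)) {
      up_map <- tapply(tab[, l + 1L], tab[, l], function(v) v[[1L]])
      expect_identical(as.character(up_map[tab[, l]]), tab[, l + 1L])
    }
  }
})

test_that("lattice sizes are exact, including beyond double precision", {
  expect_identical(lattice_size(integer()), 1)
  expect_identical(lattice_size(c(3, 1, 5, 3, 1)), 384)
  expect_error(lattice_size(c(2, -1)), "non-negative")
  # count check against explicit enumeration
  for (h in list(c(2, 1), c(3, 3), c(1, 1, 1, 1), c(4, 2, 3))) {
    expect_equal(lattice_size(h), nrow(enumerate_schemes(h)))
  }
  # 32-attribute product, frozen from an independent big-integer oracle
  h32 <- c(3, 4, 2, 5, 3, 1, 4, 2, 3, 5, 2, 4, 3, 1, 5, 2, 4, 3, 2, 5, 1, 4,
           3, 2, 5, 4, 3, 2, 1, 5, 4, 3)
  expect_identical(lattice_size(h32), "8358844170240000000")
})

test_that("lattice neighbours follow the definition and are antisymmetric", {
  expect_equal(neighbors(c(0L, 0L), c(2L, 1L), "up"),
               rbind(c(1L, 0L), c(0L, 1L)))
  expect_equal(neighbors(c(1L, 1L), c(2L, 1L), "down"),
               rbind(c(0L, 1L), c(1L, 0L)))
  expect_equal(nrow(neighbors(c(2L, 1L), c(2L, 1L), "up")), 0L)
  # antisymmetry: y in up(x) <=> x in down(y), over a whole small lattice
  heights <- c(2L, 1L, 2L)
  schemes <- enumerate_schemes(heights)
  key <- apply(schemes, 1L, paste, collapse = ",")
  up_sets <- lapply(seq_len(nrow(schemes)), function(i)
    apply(neighbors(schemes[i, ], heights, "up"), 1L, paste, collapse = ","))
  for (i in seq_len(nrow(schemes))) {
    for (j in seq_len(nrow(schemes))) {
      y_in_up_x <- key[j] %in% up_sets[[i]]
      x_in_down_y <- key[i] %in%
        apply(neighbors(schemes[j, ], heights, "down"), 1L,
              paste, collapse = ",")
      expect_identical(y_in_up_x, x_in_down_y)
    }
  }
})
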
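# Printed comparison-table fixtures used as inputs by the arithmetic checks.

# Subset-difference (Jaccard) table: per-dataset values of the proposed
# criterion's top-K subset against each competitor's. Rows 1 and 4 used
# K = 10; all other rows K = 30.
jaccard_table <- data.frame(
  mim    = c(0.667, 0.935, 0.538, 0.818, 0.017, 0.000, 0.579, 0.429, 0.034,
             0.091, 0.132, 0.017),
  ig_rfe = c(0.818, 0.935, 0.579, 0.818, 0.017, 0.017, 0.622, 0.500, 0.017,
             0.017, 0.132, 0.200),
  iwfs   = c(0.333, 0.765, 0.500, 0.333, 0.017, 0.017, 0.053, 0.224, 0.017,
             0.818, 0.034, 0.017),
  cmim   = c(0.333, 0.765, 0.463, 0.333, 0.000, 0.000, 0.224, 0.395, 0.017,
             0.000, 0.132, 0.000),
  dwfs   = c(0.429, 0.818, 0.500, 0.250, 0.132, 0.034, 0.017, 0.250, 0.091,
             0.765, 0.071, 0.071),
  cife   = c(0.176, 0.765, 0.500, 0.250, 0.000, 0.091, 0.034, 0.091, 0.017,
             0.000, 0.071, 0.000)
)
jaccard_table_k <- c(10, 30, 30, 10, rep(30, 8))

# KNN accuracy columns (percent) for the proposed criterion and the
# mutual-information-maximisation baseline, one row per dataset; plus the
# two cells quoted in the accompanying discussion of the Dermatology and
# SMK-CAN-187 rows.
knn_accuracy <- data.frame(
  ndcrfs = c(38.300, 97.769, 98.589, 97.919, 88.636, 85.480, 76.690, 87.648,
             93.000, 70.014, 95.667, 84.662),
  mim    = c(34.780, 92.164, 98.401, 97.145, 88.064, 68.037, 75.440, 85.538,
             88.000, 68.393, 84.722, 80.733)
)
knn_dermatology <- c(ndcrfs = 97.769, cife = 87.139)
knn_smk_can_187 <- c(ndcrfs = 70.014, cife = 58.876)
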
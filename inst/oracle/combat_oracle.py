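#!/usr/bin/env python
"""Independent empirical-Bayes location/scale harmonization oracle.

Reads a cohort CSV (columns: subject_id, group, site, age, sex, then
features), harmonizes across sites with age+sex covariates (effects
removed, not restored), and writes the adjusted feature matrix as CSV.
Conventions match the documented contract of the R implementation:
n-denominator per-site scale estimates, age centered at the sample mean,
parametric EB iteration to 1e-4. Used only as a cross-language test
oracle.
"""
import sys

import numpy as np
import pandas as pd

META = ["subject_id", "group", "site", "age", "sex"]


def harmonize(df):
    feats = [c for c in df.columns if c not in META]
    Y = df[feats].to_numpy(float)          # M x N
    M, N = Y.shape
    sites = sorted(df["site"].unique())
    site_idx = [np.where(df["site"].to_numpy() == s)[0] for s in sites]
    n_i = np.array([len(ix) for ix in site_idx])

    # design: site one-hot + centered age + sex
    D = np.zeros((M, len(sites) + 2))
    for k, ix in enumerate(site_idx):
        D[ix, k] = 1.0
    D[:, -2] = df["age"].to_numpy(float) - df["age"].mean()
    D[:, -1] = df["sex"].to_numpy(float)

    B, *_ = np.linalg.lstsq(D, Y, rcond=None)
    alpha = (n_i / M) @ B[: len(sites)]
    cov_part = D[:, -2:] @ B[-2:]
    resid = Y - D @ B
    var_pooled = (resid ** 2).sum(axis=0) / M
    sigma = np.sqrt(var_pooled)
    Z = (Y - cov_part - alpha) / sigma

    g_star = np.zeros((len(sites), N))
    d_star2 = np.ones((len(sites), N))
    for k, ix in enumerate(site_idx):
        Zi = Z[ix]
        g_hat = Zi.mean(axis=0)
        d_hat2 = Zi.var(axis=0)            # ddof = 0
        g_bar, tau2 = g_hat.mean(), g_hat.var(ddof=1)
        m, s2 = d_hat2.mean(), d_hat2.var(ddof=1)
        if tau2 < 1e-12:
            g_star[k], d_star2[k] = np.full(N, g_bar), d_hat2
            continue
        degenerate = s2 < 1e-12
        lam = (2 * s2 + m ** 2) / s2 if not degenerate else np.nan
        theta = (m * s2 + m ** 3) / s2 if not degenerate else np.nan
        g_old, d_old = g_hat.copy(), d_hat2.copy()
        n = len(ix)
        for _ in range(100):
            g_new = (n * tau2 * g_hat + d_old * g_bar) / (n * tau2 + d_old)
            if degenerate:
                d_new = d_old
            else:
                sum2 = ((Zi - g_new) ** 2).sum(axis=0)
                d_new = (theta + 0.5 * sum2) / (n / 2 + lam - 1)
            change = max(
                np.max(np.abs(g_new - g_old) / np.maximum(np.abs(g_old),
                                                          1e-12)),
                np.max(np.abs(d_new - d_old) / np.maximum(np.abs(d_old),
                                                          1e-12)))
            g_old, d_old = g_new, d_new
            if change <= 1e-4:
                break
        g_star[k], d_star2[k] = g_old, d_old

    out = np.empty_like(Y)
    for k, ix in enumerate(site_idx):
        out[ix] = (Z[ix] - g_star[k]) / np.sqrt(d_star2[k]) * sigma + alpha
    return pd.DataFrame(out, columns=feats)


if __name__ == "__main__":
    df = pd.read_csv(sys.argv[1])
    harmonize(df).to_csv(sys.argv[2], index=False, float_format="%.12g")
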
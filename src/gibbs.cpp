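#include <RcppEigen.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::depends(RcppEigen)]]

// Gibbs sampler for pedigree-based animal models, one or two traits. All
// matrices arrive as compressed-sparse-column arrays (dgCMatrix slots).
// Trait t has design W_t (n_t x p_t) with the genetic equations in the
// last q columns; the two-trait model couples the traits only through the
// genetic (co)variance matrix G (residual covariance fixed at zero: record
// sets are disjoint by animal).
//
// Location effects are updated by a single-site Gauss-Seidel scan every
// cycle; every `block_every` cycles the full genetic vector (both traits
// jointly) is additionally redrawn in one exact multivariate-normal block
// via a sparse Cholesky factorisation. Both moves sample from full
// conditionals of the same joint posterior, so the stationary distribution
// is unchanged; the block move is needed because single-site updates of a
// long pedigree-correlated vector mix too slowly to traverse the
// small-genetic-variance region of the posterior.

static inline double col_dot(const int *p, const int *i, const double *x,
                             int j, const double *v) {
  double s = 0.0;
  for (int k = p[j]; k < p[j + 1]; ++k) s += x[k] * v[i[k]];
  return s;
}

struct SpMat {
  const int *p;
  const int *i;
  const double *x;
  int ncol;
};

static SpMat as_spmat(const List &m) {
  SpMat out;
  out.p = INTEGER(((SEXP)m["p"]));
  out.i = INTEGER(((SEXP)m["i"]));
  out.x = REAL(((SEXP)m["x"]));
  out.ncol = as<int>(m["ncol"]);
  return out;
}

// residual sum of squares e'e with e = y - W theta
static double rss(const SpMat &W, const NumericVector &y,
                  const std::vector<double> &theta, std::vector<double> &work) {
  int n = y.size();
  for (int r = 0; r < n; ++r) work[r] = y[r];
  for (int j = 0; j < W.ncol; ++j) {
    double tj = theta[j];
    if (tj == 0.0) continue;
    for (int k = W.p[j]; k < W.p[j + 1]; ++k) work[W.i[k]] -= W.x[k] * tj;
  }
  double s = 0.0;
  for (int r = 0; r < n; ++r) s += work[r] * work[r];
  return s;
}

// u = Ainv %*% a (Ainv stored as full general sparse, symmetric values)
static void ainv_mult(const SpMat &A, const std::vector<double> &a, int off,
                      std::vector<double> &u) {
  int q = A.ncol;
  std::fill(u.begin(), u.end(), 0.0);
  for (int j = 0; j < q; ++j) {
    double aj = a[off + j];
    if (aj == 0.0) continue;
    for (int k = A.p[j]; k < A.p[j + 1]; ++k) u[A.i[k]] += A.x[k] * aj;
  }
}

// [[Rcpp::export]]
List gibbs_sampler_cpp(List traits, List ainv, NumericVector adiag,
                       List chain, List priors, List start,
                       bool update_variances, bool bivariate) {
  const int ntr = bivariate ? 2 : 1;
  std::vector<SpMat> W(ntr), WtW(ntr);
  std::vector<NumericVector> y(ntr), Wty(ntr), WtWdiag(ntr);
  std::vector<int> nfix(ntr), ptot(ntr), nrec(ntr);
  for (int t = 0; t < ntr; ++t) {
    List tr = traits[t];
    W[t] = as_spmat(tr["W"]);
    WtW[t] = as_spmat(tr["WtW"]);
    y[t] = as<NumericVector>(tr["y"]);
    Wty[t] = as<NumericVector>(tr["Wty"]);
    WtWdiag[t] = as<NumericVector>(tr["WtWdiag"]);
    nfix[t] = as<int>(tr["n_fixed"]);
    ptot[t] = WtW[t].ncol;
    nrec[t] = y[t].size();
  }
  SpMat A = as_spmat(ainv);
  const int q = A.ncol;

  const int cycles = as<int>(chain["cycles"]);
  const int burnin = as<int>(chain["burnin"]);
  const int thin = as<int>(chain["thin"]);
  const int nret = as<int>(chain["n_retained"]);
  const int block_every = as<int>(chain["block_every"]);

  const double nu_e = as<double>(priors["nu_e"]);
  const double s_e = as<double>(priors["s_e"]);
  const double nu_a = as<double>(priors["nu_a"]);
  const double s_a = as<double>(priors["s_a"]);
  const double nu_g = as<double>(priors["nu_g"]);
  NumericMatrix Sg = as<NumericMatrix>(priors["S_g"]);

  for (int t = 0; t < ntr; ++t) {
    if (nrec[t] + nu_e <= 0.0)
      stop("configuration error: residual degrees of freedom <= 0");
  }
  if (!bivariate && q + nu_a <= 0.0)
    stop("configuration error: genetic degrees of freedom <= 0");
  if (bivariate && q + nu_g <= 1.0)
    stop("configuration error: genetic degrees of freedom <= 1");

  std::vector<double> s2e(ntr);
  NumericVector s2e0 = as<NumericVector>(start["sigma2_e"]);
  for (int t = 0; t < ntr; ++t) s2e[t] = s2e0[t];
  // G (1x1 or 2x2) and its inverse
  NumericMatrix G0 = as<NumericMatrix>(start["G"]);
  double g11 = G0(0, 0), g12 = 0.0, g22 = 0.0;
  if (bivariate) { g12 = G0(0, 1); g22 = G0(1, 1); }
  double i11, i12 = 0.0, i22 = 0.0;
  if (bivariate) {
    double det = g11 * g22 - g12 * g12;
    if (det <= 0.0) stop("start G is not positive definite");
    i11 = g22 / det; i22 = g11 / det; i12 = -g12 / det;
  } else {
    i11 = 1.0 / g11;
  }

  std::vector<std::vector<double> > theta(ntr), thsum(ntr);
  for (int t = 0; t < ntr; ++t) {
    theta[t].assign(ptot[t], 0.0);
    thsum[t].assign(ptot[t], 0.0);
  }
  std::vector<double> u1(q), u2(q), work;
  int maxn = 0;
  for (int t = 0; t < ntr; ++t) if (nrec[t] > maxn) maxn = nrec[t];
  work.resize(maxn);

  // --- genetic-block machinery: precision = [Z'Z/s2e] + Ginv (x) Ainv ---
  // The sparsity pattern is fixed across cycles (Ainv pattern replicated
  // over the ntr x ntr trait blocks; the Z'Z contribution sits on the
  // diagonal, which Ainv already covers), so the symbolic factorisation
  // is done once and every block move only refills the numeric values
  // through precomputed positions and refactorises.
  const int gdim = ntr * q;
  Eigen::SparseMatrix<double> Cg(gdim, gdim);
  Eigen::SimplicialLLT<Eigen::SparseMatrix<double> > solver;
  Eigen::VectorXd grhs(gdim), gz(gdim), gmu(gdim), gw(gdim);
  const int annz = A.p[q];
  std::vector<int> posA;        // ntr*ntr blocks x annz value positions
  std::vector<int> posDiag(gdim);
  if (block_every > 0) {
    std::vector<Eigen::Triplet<double> > trips;
    trips.reserve((size_t)annz * ntr * ntr);
    for (int j = 0; j < q; ++j)
      for (int k = A.p[j]; k < A.p[j + 1]; ++k)
        for (int bt = 0; bt < ntr; ++bt)
          for (int bu = 0; bu < ntr; ++bu)
            trips.push_back(Eigen::Triplet<double>(A.i[k] + bt * q,
                                                   j + bu * q, 1.0));
    Cg.setFromTriplets(trips.begin(), trips.end());
    Cg.makeCompressed();
    solver.analyzePattern(Cg);
    // value-position lookup: binary search each (row, col) in Cg's CSC
    const int *cp = Cg.outerIndexPtr();
    const int *ci = Cg.innerIndexPtr();
    posA.resize((size_t)ntr * ntr * annz);
    for (int j = 0; j < q; ++j) {
      for (int k = A.p[j]; k < A.p[j + 1]; ++k) {
        for (int bt = 0; bt < ntr; ++bt) {
          for (int bu = 0; bu < ntr; ++bu) {
            int col = j + bu * q, rowi = A.i[k] + bt * q;
            const int *lo = ci + cp[col], *hi = ci + cp[col + 1];
            const int *it = std::lower_bound(lo, hi, rowi);
            posA[((size_t)bt * ntr + bu) * annz + k] = (int)(it - ci);
          }
        }
      }
    }
    for (int t = 0; t < ntr; ++t) {
      for (int ia = 0; ia < q; ++ia) {
        int col = t * q + ia;
        const int *lo = ci + cp[col], *hi = ci + cp[col + 1];
        const int *it = std::lower_bound(lo, hi, col);
        posDiag[col] = (int)(it - ci);
      }
    }
  }

  const int ncomp = bivariate ? 5 : 2;
  NumericMatrix draws(nret, ncomp);
  int row = 0;

  for (int c = 1; c <= cycles; ++c) {
    // --- location effects, single-site Gauss-Seidel scan ---
    for (int t = 0; t < ntr; ++t) {
      const int f = nfix[t];
      const double inv_e = 1.0 / s2e[t];
      const double gtt = bivariate ? (t == 0 ? i11 : i22) : i11;
      const double gtu = bivariate ? i12 : 0.0;
      const int u = 1 - t;
      std::vector<double> &th = theta[t];
      for (int j = 0; j < ptot[t]; ++j) {
        double dj = WtWdiag[t][j];
        if (j < f && dj == 0.0) { th[j] = 0.0; continue; }  // empty column
        double off = col_dot(WtW[t].p, WtW[t].i, WtW[t].x, j, th.data());
        double num = (Wty[t][j] - (off - dj * th[j])) * inv_e;
        double cjj = dj * inv_e;
        if (j >= f) {
          int ia = j - f;
          double ga = col_dot(A.p, A.i, A.x, ia, th.data() + f);
          double ad = adiag[ia];
          num -= gtt * (ga - ad * th[j]);
          cjj += gtt * ad;
          if (bivariate) {
            double gau = col_dot(A.p, A.i, A.x, ia, theta[u].data() + nfix[u]);
            num -= gtu * gau;
          }
        }
        double draw = num / cjj + norm_rand() / std::sqrt(cjj);
        if (!std::isfinite(draw))
          stop("non-finite location draw at cycle %d", c);
        th[j] = draw;
      }
    }

    // --- joint redraw of the genetic vector(s), exact block conditional ---
    if (block_every > 0 && c % block_every == 0) {
      double *cv = Cg.valuePtr();
      std::fill(cv, cv + Cg.nonZeros(), 0.0);
      if (!bivariate) {
        const int *p00 = posA.data();
        for (int k = 0; k < annz; ++k) cv[p00[k]] += i11 * A.x[k];
      } else {
        const int *p00 = posA.data();
        const int *p01 = posA.data() + annz;
        const int *p10 = posA.data() + 2 * (size_t)annz;
        const int *p11 = posA.data() + 3 * (size_t)annz;
        for (int k = 0; k < annz; ++k) {
          double x = A.x[k];
          cv[p00[k]] += i11 * x;
          cv[p01[k]] += i12 * x;
          cv[p10[k]] += i12 * x;
          cv[p11[k]] += i22 * x;
        }
      }
      for (int t = 0; t < ntr; ++t) {
        const int f = nfix[t];
        const double inv_e = 1.0 / s2e[t];
        for (int ia = 0; ia < q; ++ia) {
          double d = WtWdiag[t][f + ia];
          if (d != 0.0) cv[posDiag[t * q + ia]] += d * inv_e;
        }
        // rhs: Z_t' (y_t - X_t beta_t) / s2e_t
        std::vector<double> &th = theta[t];
        int n = nrec[t];
        for (int r = 0; r < n; ++r) work[r] = y[t][r];
        for (int j = 0; j < f; ++j) {
          double tj = th[j];
          if (tj == 0.0) continue;
          for (int k = W[t].p[j]; k < W[t].p[j + 1]; ++k)
            work[W[t].i[k]] -= W[t].x[k] * tj;
        }
        for (int ia = 0; ia < q; ++ia) {
          double s = 0.0;
          int j = f + ia;
          for (int k = W[t].p[j]; k < W[t].p[j + 1]; ++k)
            s += W[t].x[k] * work[W[t].i[k]];
          grhs[t * q + ia] = s * inv_e;
        }
      }
      solver.factorize(Cg);
      if (solver.info() != Eigen::Success)
        stop("genetic-block precision factorisation failed at cycle %d", c);
      gmu = solver.solve(grhs);
      for (int k = 0; k < gdim; ++k) gz[k] = norm_rand();
      gw = solver.matrixU().solve(gz);
      gw = solver.permutationPinv() * gw;
      for (int t = 0; t < ntr; ++t)
        for (int ia = 0; ia < q; ++ia) {
          double val = gmu[t * q + ia] + gw[t * q + ia];
          if (!std::isfinite(val))
            stop("non-finite genetic block draw at cycle %d", c);
          theta[t][nfix[t] + ia] = val;
        }
    }

    if (update_variances) {
      // --- residual variances, scaled inverse chi-square ---
      for (int t = 0; t < ntr; ++t) {
        double sse = rss(W[t], y[t], theta[t], work);
        double scale = sse + nu_e * s_e;
        double df = nrec[t] + nu_e;
        double val = scale / R::rchisq(df);
        if (!std::isfinite(val) || val <= 0.0)
          stop("non-finite residual variance draw at cycle %d", c);
        s2e[t] = val;
      }
      // --- genetic (co)variances ---
      if (!bivariate) {
        ainv_mult(A, theta[0], nfix[0], u1);
        double saa = 0.0;
        for (int k = 0; k < q; ++k) saa += theta[0][nfix[0] + k] * u1[k];
        double val = (saa + nu_a * s_a) / R::rchisq(q + nu_a);
        if (!std::isfinite(val) || val <= 0.0)
          stop("non-finite genetic variance draw at cycle %d", c);
        g11 = val;
        i11 = 1.0 / g11;
      } else {
        ainv_mult(A, theta[0], nfix[0], u1);
        ainv_mult(A, theta[1], nfix[1], u2);
        double S11 = 0.0, S12 = 0.0, S22 = 0.0;
        for (int k = 0; k < q; ++k) {
          double a1 = theta[0][nfix[0] + k], a2 = theta[1][nfix[1] + k];
          S11 += a1 * u1[k];
          S12 += a1 * u2[k];
          S22 += a2 * u2[k];
        }
        S11 += Sg(0, 0); S12 += Sg(0, 1); S22 += Sg(1, 1);
        // G | a ~ inverse-Wishart(S, q + nu_g); draw G^{-1} ~ Wishart via Bartlett
        double det = S11 * S22 - S12 * S12;
        if (det <= 0.0) stop("singular genetic scale matrix at cycle %d", c);
        double V11 = S22 / det, V12 = -S12 / det, V22 = S11 / det; // S^{-1}
        double L11 = std::sqrt(V11);
        double L21 = V12 / L11;
        double L22 = std::sqrt(V22 - L21 * L21);
        double df = q + nu_g;
        double b11 = std::sqrt(R::rchisq(df));
        double b21 = norm_rand();
        double b22 = std::sqrt(R::rchisq(df - 1.0));
        // T = L_lower * B_lower; Ginv = T T'
        double T11 = L11 * b11;
        double T21 = L21 * b11 + L22 * b21;
        double T22 = L22 * b22;
        i11 = T11 * T11;
        i12 = T11 * T21;
        i22 = T21 * T21 + T22 * T22;
        double deti = i11 * i22 - i12 * i12;
        if (!std::isfinite(deti) || deti <= 0.0)
          stop("non-finite genetic covariance draw at cycle %d", c);
        g11 = i22 / deti; g22 = i11 / deti; g12 = -i12 / deti;
      }
    }

    // --- retention bookkeeping: keep c iff c > burnin and (c-burnin) % thin == 0
    if (c > burnin && (c - burnin) % thin == 0 && row < nret) {
      if (!bivariate) {
        draws(row, 0) = g11;
        draws(row, 1) = s2e[0];
      } else {
        draws(row, 0) = g11;
        draws(row, 1) = g22;
        draws(row, 2) = g12;
        draws(row, 3) = s2e[0];
        draws(row, 4) = s2e[1];
      }
      for (int t = 0; t < ntr; ++t)
        for (int j = 0; j < ptot[t]; ++j) thsum[t][j] += theta[t][j];
      ++row;
    }
    if (c % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  List locmeans(ntr);
  for (int t = 0; t < ntr; ++t) {
    NumericVector m(ptot[t]);
    for (int j = 0; j < ptot[t]; ++j) m[j] = thsum[t][j] / row;
    locmeans[t] = m;
  }
  return List::create(_["draws"] = draws, _["location_means"] = locmeans,
                      _["n_retained"] = row);
}
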
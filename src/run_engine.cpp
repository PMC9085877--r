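#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---- error approximation -------------------------------------------------

static inline double approx_eps_one(double m, int mode, int k, bool half_up) {
  // mode: 0 exact, 1 stepwise, 2 k-step
  if (mode == 0) return m;
  double s;
  if (m <= 0.0) {
    s = 0.0;
  } else {
    double e = std::floor(std::log10(m));
    if (half_up) {
      double mant = m / std::pow(10.0, e);
      if (mant >= 5.0) e += 1.0;
    }
    s = std::pow(10.0, e);
    if (s > 0.1) s = 0.1;  // highest level is 1e-1
  }
  if (mode == 2) {
    double lo = std::pow(10.0, -k);
    if (s < lo) s = lo;  // lower clamp applies even at m == 0
  }
  return s;
}

// [[Rcpp::export]]
NumericVector cpp_approx_error(NumericVector m, int mode, int k, bool half_up) {
  R_xlen_t n = m.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = approx_eps_one(m[i], mode, k, half_up);
  return out;
}

// ---- small helpers -------------------------------------------------------

// Binomial sample of deaths among n units each dying with probability q.
// pmf0 = (1-q)^n must be supplied (cached by callers); exact inversion for
// small n*q, R::rbinom otherwise. Uses the R RNG.
static inline double draw_deaths(double n, double q, double pmf0) {
  if (n <= 0.0 || q <= 0.0) return 0.0;
  if (q >= 1.0) return n;
  if (n * q > 25.0) return R::rbinom(n, q);
  double u = unif_rand();
  if (u <= pmf0) return 0.0;
  double s = q / (1.0 - q), f = pmf0, cum = pmf0, kk = 0.0;
  while (u > cum && kk < n) {
    kk += 1.0;
    f *= s * (n - kk + 1.0) / kk;
    cum += f;
  }
  return kk;
}

static inline double pmf0_of(double n, double q) {
  if (q <= 0.0) return 1.0;
  if (q >= 1.0) return 0.0;
  return std::exp(n * std::log1p(-q));
}

static double pearson_or_na(const std::vector<double>& a, const NumericVector& b) {
  size_t n = a.size();
  double ma = 0, mb = 0;
  for (size_t i = 0; i < n; ++i) { ma += a[i]; mb += b[i]; }
  ma /= n; mb /= n;
  double saa = 0, sbb = 0, sab = 0;
  for (size_t i = 0; i < n; ++i) {
    double da = a[i] - ma, db = b[i] - mb;
    saa += da * da; sbb += db * db; sab += da * db;
  }
  if (saa <= 0.0 || sbb <= 0.0) return NA_REAL;
  return sab / std::sqrt(saa * sbb);
}

// Leaf ratios by path products over a preorder-indexed tree (parent id <
// child id; children: positive = pair id (1-based), negative = -leaf id).
static void leaf_ratios_into(const IntegerVector& left, const IntegerVector& right,
                             const std::vector<double>& xL, const std::vector<double>& xR,
                             std::vector<double>& cov, std::vector<double>& ratio) {
  int np = left.size();
  std::fill(cov.begin(), cov.end(), 0.0);
  cov[0] = 1.0;
  for (int i = 0; i < np; ++i) {
    double tot = xL[i] + xR[i];
    double fl = tot > 0.0 ? xL[i] / tot : 0.5;
    int lc = left[i], rc = right[i];
    if (lc > 0) cov[lc - 1] = cov[i] * fl; else ratio[-lc - 1] = cov[i] * fl;
    if (rc > 0) cov[rc - 1] = cov[i] * (1.0 - fl); else ratio[-rc - 1] = cov[i] * (1.0 - fl);
  }
}

// ---- independent pair array (single pair, hierarchy) ---------------------

// All pairs advance on one shared repetition clock; each pair runs its own
// increase (competitive amplification / additive increase) and decay
// (scaled: per-repetition survival 1 - alpha_dec*eps; gated: with
// probability alpha_dec survival 1 - eps). eps is recomputed from the
// post-increase state within the same repetition.
// [[Rcpp::export]]
List cpp_run_pairs(NumericVector xL0, NumericVector xR0, NumericVector tfracL,
                   LogicalVector noDecay,
                   double alphaInc, double alphaDec, double beta, double gamma,
                   int errMode, int kStep, bool halfUp, int decayMode,
                   double fixedEps, double nRepeats, double recordStride,
                   IntegerVector left, IntegerVector right, NumericVector targetLeaf,
                   bool recordStates, int alphaIncMode, double alphaMin,
                   int covRefreshStride) {
  int np = xL0.size();
  std::vector<double> xL(xL0.begin(), xL0.end()), xR(xR0.begin(), xR0.end());
  std::vector<double> qd(np), pmfL(np), pmfR(np), psel(np), alpha(np, alphaInc);
  std::vector<char> dirty(np, 1);
  bool haveTree = left.size() == np && np > 1;
  int nl = targetLeaf.size();
  bool recR = haveTree && nl > 0;
  std::vector<double> cov(np), ratio(nl > 0 ? nl : 1);

  bool useFixed = R_finite(fixedEps);
  double gateP = decayMode == 1 ? alphaDec : 1.0;

  // records
  std::vector<double> recT, recRv;
  std::vector<double> recXLv, recXRv;
  long nrep = (long) nRepeats;
  long stride = recordStride > 0 ? (long) recordStride : nrep;

  RNGScope scope;

  for (long t = 1; t <= nrep; ++t) {
    if (alphaIncMode == 1 && ((t - 1) % covRefreshStride == 0)) {
      // alpha_inc from current coverage: alpha_min + 0.1 * coverage(pair)
      std::fill(cov.begin(), cov.end(), 0.0);
      cov[0] = 1.0;
      for (int i = 0; i < np; ++i) {
        double tot = xL[i] + xR[i];
        double fl = tot > 0.0 ? xL[i] / tot : 0.5;
        if (left[i] > 0) cov[left[i] - 1] = cov[i] * fl;
        if (right[i] > 0) cov[right[i] - 1] = cov[i] * (1.0 - fl);
      }
      for (int i = 0; i < np; ++i) alpha[i] = alphaMin + 0.1 * cov[i];
    }
    for (int i = 0; i < np; ++i) {
      if (dirty[i]) {
        double eps;
        if (noDecay[i]) {
          eps = 0.0;
        } else if (useFixed) {
          eps = fixedEps;
        } else {
          double tot = xL[i] + xR[i];
          double cur = tot > 0.0 ? xL[i] / tot : 0.5;
          double d = cur - tfracL[i];
          eps = approx_eps_one(d * d, errMode, kStep, halfUp);
        }
        qd[i] = decayMode == 1 ? eps : alphaDec * eps;
        pmfL[i] = pmf0_of(xL[i], qd[i]);
        pmfR[i] = pmf0_of(xR[i], qd[i]);
        psel[i] = (xL[i] + beta) / (xL[i] + xR[i] + 2.0 * beta);
        dirty[i] = 0;
      }
      // increase process
      if (unif_rand() < alpha[i]) {
        bool goLeft;
        if (gamma > 0.0 && unif_rand() < gamma) goLeft = unif_rand() < 0.5;
        else goLeft = unif_rand() < psel[i];
        if (goLeft) xL[i] += 1.0; else xR[i] += 1.0;
        // eps recomputed from the post-increase state, same repetition
        dirty[i] = 1;
        {
          double eps;
          if (noDecay[i]) eps = 0.0;
          else if (useFixed) eps = fixedEps;
          else {
            double tot = xL[i] + xR[i];
            double cur = tot > 0.0 ? xL[i] / tot : 0.5;
            double d = cur - tfracL[i];
            eps = approx_eps_one(d * d, errMode, kStep, halfUp);
          }
          qd[i] = decayMode == 1 ? eps : alphaDec * eps;
          pmfL[i] = pmf0_of(xL[i], qd[i]);
          pmfR[i] = pmf0_of(xR[i], qd[i]);
          psel[i] = (xL[i] + beta) / (xL[i] + xR[i] + 2.0 * beta);
          dirty[i] = 0;
        }
      }
      // decrease process
      if (qd[i] > 0.0 && (gateP >= 1.0 || unif_rand() < gateP)) {
        double dL = draw_deaths(xL[i], qd[i], pmfL[i]);
        double dR = draw_deaths(xR[i], qd[i], pmfR[i]);
        if (dL > 0.0 || dR > 0.0) {
          xL[i] -= dL; xR[i] -= dR;
          dirty[i] = 1;
        }
      }
    }
    if (t % stride == 0 || t == nrep) {
      recT.push_back((double) t);
      if (recR) {
        leaf_ratios_into(left, right, xL, xR, cov, ratio);
        recRv.push_back(pearson_or_na(ratio, targetLeaf));
      }
      if (recordStates) {
        for (int i = 0; i < np; ++i) { recXLv.push_back(xL[i]); recXRv.push_back(xR[i]); }
      }
    }
  }

  List out = List::create(
    _["x_left"] = NumericVector(xL.begin(), xL.end()),
    _["x_right"] = NumericVector(xR.begin(), xR.end()),
    _["rec_repeat"] = NumericVector(recT.begin(), recT.end()));
  if (recR) out["rec_r"] = NumericVector(recRv.begin(), recRv.end());
  if (recordStates) {
    int nrec = recT.size();
    NumericMatrix mL(np, nrec), mR(np, nrec);
    for (int j = 0; j < nrec; ++j)
      for (int i = 0; i < np; ++i) {
        mL(i, j) = recXLv[(size_t) j * np + i];
        mR(i, j) = recXRv[(size_t) j * np + i];
      }
    out["rec_x_left"] = mL;
    out["rec_x_right"] = mR;
  }
  if (haveTree) {
    leaf_ratios_into(left, right, xL, xR, cov, ratio);
    out["leaf_ratios"] = NumericVector(ratio.begin(), ratio.end());
  }
  return out;
}

// ---- flat list -----------------------------------------------------------

// All factors compete in one list; a single shared error is the mean over
// factors of (x_i/sum(x) - T_i/sum(T))^2.
// [[Rcpp::export]]
List cpp_run_flat(NumericVector x0, NumericVector tfrac,
                  double alphaInc, double alphaDec, double beta, double gamma,
                  int errMode, int kStep, bool halfUp, int decayMode,
                  double fixedEps, double nRepeats, double recordStride) {
  int n = x0.size();
  std::vector<double> x(x0.begin(), x0.end()), pmf(n);
  double qd = 0.0;
  bool dirty = true;
  bool useFixed = R_finite(fixedEps);
  double gateP = decayMode == 1 ? alphaDec : 1.0;
  std::vector<double> recT;
  std::vector<double> recX;
  long nrep = (long) nRepeats;
  long stride = recordStride > 0 ? (long) recordStride : nrep;
  RNGScope scope;

  for (long t = 1; t <= nrep; ++t) {
    if (dirty) {
      double eps;
      if (useFixed) {
        eps = fixedEps;
      } else {
        double tot = 0.0;
        for (int i = 0; i < n; ++i) tot += x[i];
        double mse = 0.0;
        for (int i = 0; i < n; ++i) {
          double cur = tot > 0.0 ? x[i] / tot : 1.0 / n;
          double d = cur - tfrac[i];
          mse += d * d;
        }
        mse /= n;
        eps = approx_eps_one(mse, errMode, kStep, halfUp);
      }
      qd = decayMode == 1 ? eps : alphaDec * eps;
      for (int i = 0; i < n; ++i) pmf[i] = pmf0_of(x[i], qd);
      dirty = false;
    }
    if (unif_rand() < alphaInc) {
      int sel;
      if (gamma > 0.0 && unif_rand() < gamma) {
        sel = (int) std::floor(unif_rand() * n);
        if (sel >= n) sel = n - 1;
      } else {
        double tot = 0.0;
        for (int i = 0; i < n; ++i) tot += x[i] + beta;
        double u = unif_rand() * tot, cum = 0.0;
        sel = n - 1;
        for (int i = 0; i < n; ++i) { cum += x[i] + beta; if (u < cum) { sel = i; break; } }
      }
      x[sel] += 1.0;
      dirty = true;
      // recompute shared eps from the post-increase state
      {
        double eps;
        if (useFixed) eps = fixedEps;
        else {
          double tot = 0.0;
          for (int i = 0; i < n; ++i) tot += x[i];
          double mse = 0.0;
          for (int i = 0; i < n; ++i) {
            double cur = tot > 0.0 ? x[i] / tot : 1.0 / n;
            double d = cur - tfrac[i];
            mse += d * d;
          }
          mse /= n;
          eps = approx_eps_one(mse, errMode, kStep, halfUp);
        }
        qd = decayMode == 1 ? eps : alphaDec * eps;
        for (int i = 0; i < n; ++i) pmf[i] = pmf0_of(x[i], qd);
        dirty = false;
      }
    }
    if (qd > 0.0 && (gateP >= 1.0 || unif_rand() < gateP)) {
      bool changed = false;
      for (int i = 0; i < n; ++i) {
        double d = draw_deaths(x[i], qd, pmf[i]);
        if (d > 0.0) { x[i] -= d; changed = true; }
      }
      if (changed) dirty = true;
    }
    if (t % stride == 0 || t == nrep) {
      recT.push_back((double) t);
      for (int i = 0; i < n; ++i) recX.push_back(x[i]);
    }
  }

  int nrec = recT.size();
  NumericMatrix mX(n, nrec);
  for (int j = 0; j < nrec; ++j)
    for (int i = 0; i < n; ++i) mX(i, j) = recX[(size_t) j * n + i];
  return List::create(_["x"] = NumericVector(x.begin(), x.end()),
                      _["rec_repeat"] = NumericVector(recT.begin(), recT.end()),
                      _["rec_x"] = mX);
}

// ---- mRNA pool / tree-descent transcription ------------------------------

// Per repetition: an entry pair is chosen among pairs in the top
// `maxEntryLayer` layers with probability proportional to coverage;
// competitive amplification descends from it to a single leaf gene; the
// pool replaces one uniformly chosen mRNA with one of the selected gene;
// pairs then decay by approximated-MSE gated at alphaDec.
// [[Rcpp::export]]
List cpp_run_pool(IntegerVector left, IntegerVector right, IntegerVector layer,
                  NumericVector xL0, NumericVector xR0, NumericVector tfracL,
                  LogicalVector noDecay, NumericVector counts0,
                  double beta, double alphaDec, int errMode, int kStep, bool halfUp,
                  int maxEntryLayer, double nRepeats, double recordStride,
                  NumericVector targetLeaf, int decayEvent, IntegerVector trackGenes) {
  int np = xL0.size();
  int nl = counts0.size();
  std::vector<double> xL(xL0.begin(), xL0.end()), xR(xR0.begin(), xR0.end());
  std::vector<double> cov(np), ratio(nl);

  // entry candidates: pairs in layers 1..maxEntryLayer (preorder => parents first)
  std::vector<int> cand;
  for (int i = 0; i < np; ++i) if (layer[i] <= maxEntryLayer) cand.push_back(i);

  // pool as a flat vector of gene ids for O(1) replacement
  long poolSize = 0;
  for (int g = 0; g < nl; ++g) poolSize += (long) counts0[g];
  if (poolSize <= 0) stop("empty mRNA pool");
  std::vector<int> poolArr((size_t) poolSize);
  std::vector<double> counts(counts0.begin(), counts0.end());
  {
    size_t pos = 0;
    for (int g = 0; g < nl; ++g)
      for (long c = 0; c < (long) counts0[g]; ++c) poolArr[pos++] = g;
  }

  std::vector<int> perm(np);
  for (int i = 0; i < np; ++i) perm[i] = i;

  int ntrack = trackGenes.size();
  std::vector<double> recT, recRpool, recRprob, recTrack;
  long nrep = (long) nRepeats;
  long stride = recordStride > 0 ? (long) recordStride : nrep;
  RNGScope scope;

  for (long t = 1; t <= nrep; ++t) {
    // coverage of candidate pairs from current branch ratios
    std::fill(cov.begin(), cov.end(), 0.0);
    cov[0] = 1.0;
    double covTot = 0.0;
    for (size_t ci = 0; ci < cand.size(); ++ci) {
      int i = cand[ci];
      double tot = xL[i] + xR[i];
      double fl = tot > 0.0 ? xL[i] / tot : 0.5;
      if (left[i] > 0 && layer[left[i] - 1] <= maxEntryLayer) cov[left[i] - 1] = cov[i] * fl;
      if (right[i] > 0 && layer[right[i] - 1] <= maxEntryLayer) cov[right[i] - 1] = cov[i] * (1.0 - fl);
      covTot += cov[i];
    }
    // entry pair ~ coverage
    int entry = cand[0];
    if (covTot > 0.0) {
      double u = unif_rand() * covTot, cum = 0.0;
      for (size_t ci = 0; ci < cand.size(); ++ci) {
        cum += cov[cand[ci]];
        if (u < cum) { entry = cand[ci]; break; }
      }
    }
    // descent by competitive amplification to a single gene
    int node = entry, gene = -1;
    while (true) {
      double pl = (xL[node] + beta) / (xL[node] + xR[node] + 2.0 * beta);
      bool goLeft = unif_rand() < pl;
      int child;
      if (goLeft) { xL[node] += 1.0; child = left[node]; }
      else        { xR[node] += 1.0; child = right[node]; }
      if (child > 0) node = child - 1;
      else { gene = -child - 1; break; }
    }
    // pool replacement: remove one uniformly chosen mRNA, add the new one
    {
      long j = (long) std::floor(unif_rand() * poolSize);
      if (j >= poolSize) j = poolSize - 1;
      counts[poolArr[(size_t) j]] -= 1.0;
      poolArr[(size_t) j] = gene;
      counts[gene] += 1.0;
    }
    // gated decay: each pair enters the decrease process at alphaDec
    int K;
    if (decayEvent == 1) {
      K = unif_rand() < alphaDec ? np : 0;
      for (int i = 0; i < K; ++i) perm[i] = i;
    } else {
      K = (int) R::rbinom((double) np, alphaDec);
      for (int i = 0; i < K; ++i) {
        int j = i + (int) std::floor(unif_rand() * (np - i));
        if (j >= np) j = np - 1;
        std::swap(perm[i], perm[j]);
      }
    }
    for (int i = 0; i < K; ++i) {
      int p = perm[i];
      if (noDecay[p]) continue;
      double tot = xL[p] + xR[p];
      double cur = tot > 0.0 ? xL[p] / tot : 0.5;
      double d = cur - tfracL[p];
      double eps = approx_eps_one(d * d, errMode, kStep, halfUp);
      if (eps <= 0.0) continue;
      xL[p] -= draw_deaths(xL[p], eps, pmf0_of(xL[p], eps));
      xR[p] -= draw_deaths(xR[p], eps, pmf0_of(xR[p], eps));
    }
    if (t % stride == 0 || t == nrep) {
      recT.push_back((double) t);
      if (targetLeaf.size() == nl) {
        recRpool.push_back(pearson_or_na(counts, targetLeaf));
        leaf_ratios_into(left, right, xL, xR, cov, ratio);
        recRprob.push_back(pearson_or_na(ratio, targetLeaf));
      }
      for (int g = 0; g < ntrack; ++g) recTrack.push_back(counts[trackGenes[g] - 1]);
    }
  }

  List out = List::create(
    _["x_left"] = NumericVector(xL.begin(), xL.end()),
    _["x_right"] = NumericVector(xR.begin(), xR.end()),
    _["counts"] = NumericVector(counts.begin(), counts.end()),
    _["rec_repeat"] = NumericVector(recT.begin(), recT.end()),
    _["rec_r_pool"] = NumericVector(recRpool.begin(), recRpool.end()),
    _["rec_r_prob"] = NumericVector(recRprob.begin(), recRprob.end()));
  if (ntrack > 0) {
    int nrec = recT.size();
    NumericMatrix mT(ntrack, nrec);
    for (int j = 0; j < nrec; ++j)
      for (int g = 0; g < ntrack; ++g) mT(g, j) = recTrack[(size_t) j * ntrack + g];
    out["rec_track"] = mT;
  }
  return out;
}
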
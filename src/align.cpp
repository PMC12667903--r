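// Structural alignment kernels: Kabsch superposition, TM-score with
// iterative subset refinement, a 3-state (affine, zero gap extension,
// free end gaps) global DP over a similarity matrix, and the iterative
// superpose/score/DP alignment heuristic they combine into.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double NEG = -1e18;

// proper-rotation least-squares superposition: X*R + t ~ Y (row vectors)
static void kabsch_core(const arma::mat& X, const arma::mat& Y,
                        arma::mat& R, arma::rowvec& t, double& rmsd,
                        double& sv_ratio) {
  arma::rowvec cx = arma::mean(X, 0), cy = arma::mean(Y, 0);
  arma::mat Xc = X.each_row() - cx, Yc = Y.each_row() - cy;
  arma::mat H = Xc.t() * Yc;
  arma::mat U, V; arma::vec s;
  arma::svd(U, s, V, H);
  arma::mat D = arma::eye(3, 3);
  if (arma::det(U * V.t()) < 0) D(2, 2) = -1;
  R = U * D * V.t();
  t = cy - cx * R;
  arma::mat diff = Xc * R - Yc;
  rmsd = std::sqrt(arma::mean(arma::sum(arma::square(diff), 1)));
  sv_ratio = s(0) > 0 ? s(1) / s(0) : 0.0;
}

// [[Rcpp::export]]
List cpp_kabsch(const arma::mat& X, const arma::mat& Y) {
  if (X.n_rows != Y.n_rows || X.n_rows < 3 || X.n_cols != 3 || Y.n_cols != 3)
    stop("kabsch needs matching m x 3 matrices with m >= 3");
  arma::mat R; arma::rowvec t; double rmsd, svr;
  kabsch_core(X, Y, R, t, rmsd, svr);
  return List::create(_["rotation"] = R, _["translation"] = t,
                      _["rmsd"] = rmsd, _["degenerate"] = (svr < 1e-8));
}

static double d0_of(int L) {
  if (L <= 15) return 0.5;
  double d0 = 1.24 * std::cbrt((double)L - 15.0) - 1.8;
  return d0 < 0.5 ? 0.5 : d0;
}

// [[Rcpp::export]]
double cpp_d0(int L) { return d0_of(L); }

// 3-state DP, gap-open go (negative), gap extension 0, end gaps free.
// Objective: sum of S over matched pairs + go per internal gap opening
// (query-side and target-side openings counted separately).
// [[Rcpp::export]]
List cpp_dp(const arma::mat& S, double go) {
  int n = S.n_rows, m = S.n_cols;
  arma::mat M(n + 1, m + 1), Ix(n + 1, m + 1), Iy(n + 1, m + 1);
  M.fill(NEG); Ix.fill(NEG); Iy.fill(NEG);
  arma::imat pM(n + 1, m + 1), pIx(n + 1, m + 1), pIy(n + 1, m + 1);
  pM.fill(-1); pIx.fill(-1); pIy.fill(-1);
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M: match i-j
      double a = M(i - 1, j - 1), b = Ix(i - 1, j - 1), c = Iy(i - 1, j - 1);
      double best = 0.0; int ptr = 3;           // 3 = fresh start (free lead)
      if (a >= best) { best = a; ptr = 0; }
      if (b > best) { best = b; ptr = 1; }
      if (c > best) { best = c; ptr = 2; }
      M(i, j) = S(i - 1, j - 1) + best;
      pM(i, j) = ptr;
      // Ix: query residue i unmatched
      a = M(i - 1, j) + go; b = Ix(i - 1, j); c = Iy(i - 1, j) + go;
      if (a >= b && a >= c) { Ix(i, j) = a; pIx(i, j) = 0; }
      else if (b >= c)      { Ix(i, j) = b; pIx(i, j) = 1; }
      else                  { Ix(i, j) = c; pIx(i, j) = 2; }
      // Iy: target residue j unmatched
      a = M(i, j - 1) + go; b = Iy(i, j - 1); c = Ix(i, j - 1) + go;
      if (a >= b && a >= c) { Iy(i, j) = a; pIy(i, j) = 0; }
      else if (b >= c)      { Iy(i, j) = b; pIy(i, j) = 1; }
      else                  { Iy(i, j) = c; pIy(i, j) = 2; }
    }
  }
  int bi = 1, bj = 1; double bs = NEG;          // free trailing gaps
  for (int i = 1; i <= n; ++i)
    for (int j = 1; j <= m; ++j)
      if (M(i, j) > bs) { bs = M(i, j); bi = i; bj = j; }
  std::vector<int> qi, tj;
  int i = bi, j = bj, st = 0;                   // start in M
  while (i > 0 && j > 0) {
    if (st == 0) {
      qi.push_back(i); tj.push_back(j);
      int p = pM(i, j);
      --i; --j;
      if (p == 3) break;
      st = p;
    } else if (st == 1) {
      int p = pIx(i, j); --i; st = p;
    } else {
      int p = pIy(i, j); --j; st = p;
    }
  }
  std::reverse(qi.begin(), qi.end());
  std::reverse(tj.begin(), tj.end());
  return List::create(_["score"] = bs,
                      _["qi"] = IntegerVector(qi.begin(), qi.end()),
                      _["tj"] = IntegerVector(tj.begin(), tj.end()));
}

// TM contribution of superposed pairs (P already transformed)
static double tm_of(const arma::mat& P, const arma::mat& Q,
                    double d02, int Lnorm) {
  arma::vec d2 = arma::sum(arma::square(P - Q), 1);
  return arma::accu(1.0 / (1.0 + d2 / d02)) / (double)Lnorm;
}

// TM-score of a fixed residue mapping, maximized over superpositions by
// iterative subset refinement (windows of shrinking length seed subsets;
// each subset is superposed, scored over all mapped pairs, and replaced by
// the close pairs until stable).
// [[Rcpp::export]]
double cpp_tm_score(const arma::mat& XA, const arma::mat& XB,
                    const IntegerVector& qi, const IntegerVector& tj,
                    int Lnorm) {
  int m = qi.size();
  if (m < 1) stop("empty mapping");
  arma::mat P(m, 3), Q(m, 3);
  for (int r = 0; r < m; ++r) {
    P.row(r) = XA.row(qi[r] - 1);
    Q.row(r) = XB.row(tj[r] - 1);
  }
  double d0 = d0_of(Lnorm), d02 = d0 * d0;
  if (m < 3) {  // too few pairs to superpose; best effort: exact overlay
    return (double)m / (double)Lnorm;  // distance 0 upper bound at m<3
  }
  double best = 0.0;
  arma::mat R; arma::rowvec t; double rmsd, svr;
  for (int Lini = m; Lini >= 4 || Lini == m; Lini /= 2) {
    int L = std::max(Lini, 4 > m ? m : 4);
    int stride = std::max(L / 2, 1);
    for (int s0 = 0; s0 + L <= m; s0 += stride) {
      arma::uvec sub(L);
      for (int r = 0; r < L; ++r) sub(r) = s0 + r;
      for (int it = 0; it < 20; ++it) {
        if (sub.n_elem < 3) break;
        kabsch_core(P.rows(sub), Q.rows(sub), R, t, rmsd, svr);
        arma::mat PT = P * R;
        PT.each_row() += t;
        double tm = tm_of(PT, Q, d02, Lnorm);
        if (tm > best) best = tm;
        arma::vec d2 = arma::sum(arma::square(PT - Q), 1);
        double dc = d0;
        arma::uvec sel = arma::find(d2 < dc * dc);
        while (sel.n_elem < 3) { dc += 0.5; sel = arma::find(d2 < dc * dc); }
        if (sel.n_elem == sub.n_elem && arma::all(sel == sub)) break;
        sub = sel;
      }
      if (L == m) break;  // only one full-length window
    }
    if (Lini <= 4) break;
  }
  return best;
}

// quick min-normalized TM pair for mapping selection (single superposition)
static double quick_tm_min(const arma::mat& X, const arma::mat& Y,
                           const std::vector<int>& qi,
                           const std::vector<int>& tj) {
  int m = qi.size(), n = X.n_rows, mm = Y.n_rows;
  if (m < 3) return 0.0;
  arma::mat P(m, 3), Q(m, 3);
  for (int r = 0; r < m; ++r) {
    P.row(r) = X.row(qi[r] - 1);
    Q.row(r) = Y.row(tj[r] - 1);
  }
  arma::mat R; arma::rowvec t; double rmsd, svr;
  kabsch_core(P, Q, R, t, rmsd, svr);
  arma::mat PT = P * R; PT.each_row() += t;
  double dq = d0_of(n), dt = d0_of(mm);
  double tq = tm_of(PT, Q, dq * dq, n), tt = tm_of(PT, Q, dt * dt, mm);
  return tq < tt ? tq : tt;
}

// iterative alignment heuristic: seeds from gapless threading and fragment
// superpositions; each seed refined by {superpose on mapped set -> TM-style
// score matrix -> DP -> new mapping}; best mapping by min-normalized TM.
// [[Rcpp::export]]
List cpp_align(const arma::mat& X, const arma::mat& Y, double go = -0.6,
               int maxit = 30, int frag = 20) {
  int n = X.n_rows, m = Y.n_rows;
  double d0 = d0_of(n < m ? n : m), d02 = d0 * d0;
  std::vector<std::pair<std::vector<int>, std::vector<int> > > seeds;
  // (a) gapless threading of the shorter chain at all offsets
  if (n <= m) {
    for (int off = 0; off <= m - n; ++off) {
      std::vector<int> qi(n), tj(n);
      for (int i = 0; i < n; ++i) { qi[i] = i + 1; tj[i] = i + 1 + off; }
      seeds.push_back(std::make_pair(qi, tj));
    }
  } else {
    for (int off = 0; off <= n - m; ++off) {
      std::vector<int> qi(m), tj(m);
      for (int j = 0; j < m; ++j) { qi[j] = j + 1 + off; tj[j] = j + 1; }
      seeds.push_back(std::make_pair(qi, tj));
    }
  }
  // (b) fragment-pair superpositions
  int f = std::min(frag, n < m ? n : m);
  for (int ia = 0; ia + f <= n; ia += f)
    for (int jb = 0; jb + f <= m; jb += f) {
      std::vector<int> qi(f), tj(f);
      for (int r = 0; r < f; ++r) { qi[r] = ia + r + 1; tj[r] = jb + r + 1; }
      seeds.push_back(std::make_pair(qi, tj));
    }
  // stage 1: one superpose->score->DP sweep per seed; rank the resulting
  // mappings and keep the best few for full refinement
  arma::mat Rq; arma::rowvec tq; double rmsdq, svrq;
  std::vector<std::pair<double, size_t> > ranked;
  std::vector<std::pair<std::vector<int>, std::vector<int> > > swept(
      seeds.size());
  for (size_t s = 0; s < seeds.size(); ++s) {
    std::vector<int>& qi = seeds[s].first;
    std::vector<int>& tj = seeds[s].second;
    if ((int)qi.size() < 3) continue;
    arma::mat P(qi.size(), 3), Q(qi.size(), 3);
    for (size_t r = 0; r < qi.size(); ++r) {
      P.row(r) = X.row(qi[r] - 1);
      Q.row(r) = Y.row(tj[r] - 1);
    }
    kabsch_core(P, Q, Rq, tq, rmsdq, svrq);
    arma::mat XT = X * Rq; XT.each_row() += tq;
    arma::mat S(n, m);
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < m; ++j) {
        double dx = XT(i, 0) - Y(j, 0), dy = XT(i, 1) - Y(j, 1),
               dz = XT(i, 2) - Y(j, 2);
        S(i, j) = 1.0 / (1.0 + (dx * dx + dy * dy + dz * dz) / d02);
      }
    List dp = cpp_dp(S, go);
    IntegerVector nqi = dp["qi"], ntj = dp["tj"];
    swept[s] = std::make_pair(std::vector<int>(nqi.begin(), nqi.end()),
                              std::vector<int>(ntj.begin(), ntj.end()));
    ranked.push_back(std::make_pair(
        -quick_tm_min(X, Y, swept[s].first, swept[s].second), s));
  }
  std::sort(ranked.begin(), ranked.end());
  size_t n_keep = ranked.size() < 8 ? ranked.size() : 8;
  // stage 2: full iterative refinement of the top mappings
  double best_score = -1.0;
  std::vector<int> best_qi, best_tj;
  if (!ranked.empty()) {
    size_t s0 = ranked[0].second;
    best_score = -ranked[0].first;
    best_qi = swept[s0].first; best_tj = swept[s0].second;
  }
  arma::mat R; arma::rowvec t; double rmsd, svr;
  for (size_t rs = 0; rs < n_keep; ++rs) {
    size_t s = ranked[rs].second;
    std::vector<int> qi = swept[s].first, tj = swept[s].second;
    std::vector<int> prev_qi, prev_tj;
    for (int it = 0; it < maxit; ++it) {
      if ((int)qi.size() < 3) break;
      arma::mat P(qi.size(), 3), Q(qi.size(), 3);
      for (size_t r = 0; r < qi.size(); ++r) {
        P.row(r) = X.row(qi[r] - 1);
        Q.row(r) = Y.row(tj[r] - 1);
      }
      kabsch_core(P, Q, R, t, rmsd, svr);
      arma::mat XT = X * R; XT.each_row() += t;
      arma::mat S(n, m);
      for (int i = 0; i < n; ++i)
        for (int j = 0; j < m; ++j) {
          double dx = XT(i, 0) - Y(j, 0), dy = XT(i, 1) - Y(j, 1),
                 dz = XT(i, 2) - Y(j, 2);
          S(i, j) = 1.0 / (1.0 + (dx * dx + dy * dy + dz * dz) / d02);
        }
      List dp = cpp_dp(S, go);
      IntegerVector nqi = dp["qi"], ntj = dp["tj"];
      std::vector<int> qi2(nqi.begin(), nqi.end()),
                       tj2(ntj.begin(), ntj.end());
      double sc = quick_tm_min(X, Y, qi2, tj2);
      if (sc > best_score) { best_score = sc; best_qi = qi2; best_tj = tj2; }
      bool same = (qi2 == qi && tj2 == tj) ||
                  (qi2 == prev_qi && tj2 == prev_tj);
      prev_qi = qi; prev_tj = tj;
      qi = qi2; tj = tj2;
      if (same) break;
    }
  }
  if (best_qi.empty()) {  // degenerate fallback: best threading seed as-is
    best_qi = seeds[0].first; best_tj = seeds[0].second;
  }
  return List::create(_["qi"] = IntegerVector(best_qi.begin(), best_qi.end()),
                      _["tj"] = IntegerVector(best_tj.begin(), best_tj.end()));
}
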
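// Population-game engine for the iterated Prisoner's Dilemma:
// memory-one / tag-based / information players, round-robin single-move
// generations with move noise, imitation and Moran updating, fixation runs,
// infogain identification batches and the groupmax strategy optimizer.
//
// Moves: 0 = C, 1 = D. Outcomes (focal perspective): CC=0, CD=1, DC=2, DD=3.

#include <Rcpp.h>
#include <cmath>
#include <string>
#include <vector>

#include "md5.h"
#include "pd.h"
#include "rng.h"

using namespace Rcpp;
using ipdpop_pd::SWAP;
using ipdpop_pd::eff1;
using ipdpop_pd::eff4;
using ipdpop_pd::pd_score;
using ipdpop_rng::RNG;
using ipdpop_rng::stream_seed;

static const double LOG_CLAMP_LO = 1e-12;

static inline double clamp_prob(double x) {
  if (x < LOG_CLAMP_LO) return LOG_CLAMP_LO;
  if (x > 1.0 - LOG_CLAMP_LO) return 1.0 - LOG_CLAMP_LO;
  return x;
}

static inline double sigmoid(double L) { return 1.0 / (1.0 + std::exp(-L)); }

// upper binomial tail P(E >= e | n, eps)
static inline double binom_tail(int e, int n, double eps) {
  if (e <= 0) return 1.0;
  if (e > n) return 0.0;
  return R::pbinom(e - 1, n, eps, 0, 0);
}

// ---------------------------------------------------------------------------
// infogain move selection

static int infogain_move_c(const double n[4], const double m[4], int last,
                           const std::string& hist) {
  double pc = (last < 0) ? 0.5 : (m[last] + 1.0) / (n[last] + 2.0);
  double eC = pc * n[0] + (1.0 - pc) * n[1];
  double eD = pc * n[2] + (1.0 - pc) * n[3];
  if (eC < eD) return 0;
  if (eD < eC) return 1;
  return ipdpop_md5::md5_lsb(hist);
}

// ---------------------------------------------------------------------------
// groupmax optimization (Eq.-2-style objective)

struct GMObjective {
  double pe[4];  // noise-adjusted opponent estimate
  double Sx[4], Sy[4];
  double c1, c2, eps;
  double operator()(const double q[4]) const {
    double qe[4];
    eff4(q, eps, qe);
    double s_q = pd_score(qe, pe, Sx);   // S(q, pbar)
    double s_p = pd_score(pe, qe, Sx);   // S(pbar, q)
    (void)Sy;
    return c1 * s_q - c2 * s_p;
  }
};

static const double BOX_LO = 1e-3, BOX_HI = 1.0 - 1e-3;

static inline double boxclamp(double x) {
  if (x < BOX_LO) return BOX_LO;
  if (x > BOX_HI) return BOX_HI;
  return x;
}

// projected gradient ascent from one start; returns objective value
static double gm_ascend(const GMObjective& obj, double q[4]) {
  for (int k = 0; k < 4; ++k) q[k] = boxclamp(q[k]);
  double f = obj(q);
  double step = 0.05;
  const double h = 1e-5;
  for (int it = 0; it < 500; ++it) {
    double g[4];
    for (int k = 0; k < 4; ++k) {
      double qp[4], qm[4];
      for (int j = 0; j < 4; ++j) { qp[j] = q[j]; qm[j] = q[j]; }
      qp[k] = boxclamp(q[k] + h);
      qm[k] = boxclamp(q[k] - h);
      double denom = qp[k] - qm[k];
      g[k] = (denom > 0) ? (obj(qp) - obj(qm)) / denom : 0.0;
    }
    double gn = std::sqrt(g[0] * g[0] + g[1] * g[1] + g[2] * g[2] + g[3] * g[3]);
    if (gn < 1e-10) break;
    bool improved = false;
    double fnew = f;
    double cand[4];
    while (step > 1e-9) {
      for (int k = 0; k < 4; ++k) cand[k] = boxclamp(q[k] + step * g[k] / gn);
      fnew = obj(cand);
      if (fnew > f) { improved = true; break; }
      step *= 0.5;
    }
    if (!improved) break;
    double gain = fnew - f;
    for (int k = 0; k < 4; ++k) q[k] = cand[k];
    f = fnew;
    step = std::min(step * 2.0, 0.2);
    if (gain < 1e-6 && it > 2) break;
  }
  return f;
}

// mode 0: full multi-start (ALLC, ALLD, TFT, WSLS, pbar, prev).
// mode 1: tracking - ascend from prev and from the best raw canonical
// candidate; cheap, yet still hops basins when the objective's optimum
// switches corner (the defend -> attack transition as mbar grows).
static double gm_optimize(const double pbar[4], double mbar, int N,
                          const double Sx[4], const double Sy[4], double eps,
                          const double* prev, int mode, double out[4]) {
  GMObjective obj;
  eff4(pbar, eps, obj.pe);
  for (int k = 0; k < 4; ++k) { obj.Sx[k] = Sx[k]; obj.Sy[k] = Sy[k]; }
  obj.c1 = (N - mbar) / (N - 1.0);
  obj.c2 = mbar / (N - 1.0);
  obj.eps = eps;

  static const double ALLC[4] = {1, 1, 1, 1}, ALLD[4] = {0, 0, 0, 0},
                      TFT[4] = {1, 0, 1, 0}, WSLS[4] = {1, 0, 0, 1};
  std::vector<const double*> starts;
  if (mode == 1 && prev) {
    const double* cand[5] = {ALLC, ALLD, TFT, WSLS, pbar};
    const double* bestc = cand[0];
    double bestv = -1e300;
    for (const double* c : cand) {
      double qc[4] = {boxclamp(c[0]), boxclamp(c[1]), boxclamp(c[2]), boxclamp(c[3])};
      double v = obj(qc);
      if (v > bestv) { bestv = v; bestc = c; }
    }
    starts = {prev, bestc};
  } else {
    starts = {ALLC, ALLD, TFT, WSLS, pbar};
    if (prev) starts.push_back(prev);
  }
  double best = -1e300;
  for (const double* s0 : starts) {
    double q[4] = {s0[0], s0[1], s0[2], s0[3]};
    double val = gm_ascend(obj, q);
    if (val > best) {
      best = val;
      for (int k = 0; k < 4; ++k) out[k] = q[k];
    }
  }
  return best;
}

// ---------------------------------------------------------------------------
// player specs and per-opponent models

struct PSpec {
  int kind;  // 0 memory_one, 1 tag_based, 2 ip0, 3 conswitch
  double v[4];
  int fm;                    // memory-one first move
  double vs[4], vo[4];
  int fm_s, fm_o;            // tag-based first moves
  int ig_len;
  double alpha, hswitch, eps_a;  // eps_a < 0: use ambient epsilon
  int type_id;
};

static PSpec parse_spec(const List& sp, int type_id) {
  PSpec s;
  std::memset(&s, 0, sizeof(PSpec));
  std::string kind = as<std::string>(sp["kind"]);
  s.type_id = type_id;
  s.ig_len = 10;
  s.alpha = 0.01;
  s.hswitch = 0.01;
  s.eps_a = -1.0;
  auto getv = [&](const char* nm, double* dst) {
    NumericVector v = sp[nm];
    for (int k = 0; k < 4; ++k) dst[k] = v[k];
  };
  auto getmove = [&](const char* nm, int dflt) -> int {
    if (!sp.containsElementNamed(nm)) return dflt;
    std::string mv = as<std::string>(sp[nm]);
    return mv == "D" ? 1 : 0;
  };
  if (kind == "memory_one") {
    s.kind = 0;
    getv("vector", s.v);
    s.fm = getmove("first_move", 0);
  } else if (kind == "tag_based") {
    s.kind = 1;
    getv("vs_self", s.vs);
    getv("vs_other", s.vo);
    s.fm_s = getmove("first_move_self", 0);
    s.fm_o = getmove("first_move_other", 0);
  } else if (kind == "ip0" || kind == "conswitch") {
    s.kind = (kind == "ip0") ? 2 : 3;
    if (sp.containsElementNamed("infogain_length")) s.ig_len = as<int>(sp["infogain_length"]);
    if (sp.containsElementNamed("alpha")) s.alpha = as<double>(sp["alpha"]);
    if (sp.containsElementNamed("hmm_switch_prob")) s.hswitch = as<double>(sp["hmm_switch_prob"]);
    if (sp.containsElementNamed("epsilon_assumed")) {
      RObject ea = sp["epsilon_assumed"];
      if (!ea.isNULL()) s.eps_a = as<double>(ea);
    }
  } else {
    stop("unknown player kind: %s", kind.c_str());
  }
  return s;
}

struct OppModel {
  double n[4], m[4];    // opponent-next-move counts (my-perspective outcomes)
  double n2[4], m2[4];  // mirror: my next moves, opponent-perspective outcomes
  int rounds, e;
  double L, L_other, hmm_allc;
  bool confident;
  std::string hist_mine, hist_opp;
  int pend_pred, pend_intent;
  void reset(double prior) {
    for (int k = 0; k < 4; ++k) n[k] = m[k] = n2[k] = m2[k] = 0.0;
    rounds = 0; e = 0;
    L = prior; L_other = prior;
    hmm_allc = 0.5;
    confident = false;
    hist_mine.clear(); hist_opp.clear();
    pend_pred = -1; pend_intent = -1;
  }
};

struct IPState {
  std::vector<OppModel> mod;
  double sn[4], sm[4];  // saved counts from confidently-GP dead players
  double gp[4];
  bool has_gp;
  double prev[4];
  bool has_prev;
  double mbar;
  double pooled_th[4];
  bool has_pooled;
  double last_pbar[4], last_mbar;
  long opt_calls;
  void init(int N, double prior) {
    mod.assign(N, OppModel());
    for (auto& M : mod) M.reset(prior);
    for (int k = 0; k < 4; ++k) { sn[k] = sm[k] = 0.0; gp[k] = 0.5; prev[k] = 0.5; pooled_th[k] = 0.5; last_pbar[k] = -1; }
    has_gp = false; has_prev = false; has_pooled = false;
    mbar = 1.0; last_mbar = -1;
    opt_calls = 0;
  }
};

// ---------------------------------------------------------------------------
// the population engine

struct Engine {
  int N;
  double eps, sigma;
  int rule;  // 0 imitation, 1 moran
  std::vector<PSpec> specs;
  std::vector<int> sp;       // slot -> spec index
  std::vector<signed char> out;  // N*N last outcomes, -1 none
  std::vector<double> fit;
  std::vector<IPState> ip;
  double Sx[4], Sy[4];
  RNG rng;
  int gen;

  Engine(const std::vector<PSpec>& specs_, const std::vector<int>& assign,
         double rstp[4], double eps_, double sigma_, int rule_, uint64_t seed)
      : N((int)assign.size()), eps(eps_), sigma(sigma_), rule(rule_),
        specs(specs_), sp(assign), out((size_t)N * N, -1), fit(N, 0.0),
        ip(N), rng(seed), gen(0) {
    Sx[0] = rstp[0]; Sx[1] = rstp[1]; Sx[2] = rstp[2]; Sx[3] = rstp[3];
    Sy[0] = rstp[0]; Sy[1] = rstp[2]; Sy[2] = rstp[1]; Sy[3] = rstp[3];
    for (int i = 0; i < N; ++i)
      if (specs[sp[i]].kind >= 2) ip[i].init(N, std::log(1.0 / N));
  }

  double eps_for(const PSpec& s) const { return s.eps_a < 0 ? eps : s.eps_a; }

  // posterior-mean cooperation probability the observer assigns to opponent j
  double gp_theta(const IPState& st, const OppModel& M, int prev) const {
    if (prev < 0) return 0.5;
    if (st.has_pooled) return st.pooled_th[prev];
    return (M.m[prev] + 1.0) / (M.n[prev] + 2.0);
  }

  void prepare_slot(int i) {
    const PSpec& s = specs[sp[i]];
    IPState& st = ip[i];
    if (s.kind == 2) {
      double mb = 1.0;
      bool any_gm = false, any_conf = false;
      double pn[4], pm[4], gn[4], gm_[4], an[4], am[4];
      for (int k = 0; k < 4; ++k) {
        pn[k] = st.sn[k]; pm[k] = st.sm[k];
        gn[k] = gm_[k] = an[k] = am[k] = 0.0;
      }
      double saved_tot = pn[0] + pn[1] + pn[2] + pn[3];
      if (saved_tot > 0) any_conf = true;
      double logalpha = std::log(s.alpha);
      for (int j = 0; j < N; ++j) {
        if (j == i) continue;
        const OppModel& M = st.mod[j];
        mb += sigmoid(M.L);
        if (M.rounds >= s.ig_len) any_gm = true;
        bool conf = M.confident || (M.L < logalpha);
        for (int k = 0; k < 4; ++k) {
          if (conf) { pn[k] += M.n[k]; pm[k] += M.m[k]; }
          if (M.L <= 0) { gn[k] += M.n[k]; gm_[k] += M.m[k]; }
          an[k] += M.n[k]; am[k] += M.m[k];
        }
        if (conf) any_conf = true;
      }
      st.mbar = std::min(std::max(mb, 1.0), (double)N);
      st.has_pooled = any_conf;
      if (any_conf)
        for (int k = 0; k < 4; ++k) st.pooled_th[k] = (pm[k] + 1.0) / (pn[k] + 2.0);
      if (any_gm) {
        double th[4], pb[4];
        if (any_conf) {
          for (int k = 0; k < 4; ++k) th[k] = st.pooled_th[k];
        } else {
          double tg = gn[0] + gn[1] + gn[2] + gn[3];
          const double* nn = (tg > 0) ? gn : an;
          const double* mm = (tg > 0) ? gm_ : am;
          for (int k = 0; k < 4; ++k) th[k] = (mm[k] + 1.0) / (nn[k] + 2.0);
        }
        // theta conditions on MY-perspective outcomes; the opponent's
        // strategy vector in its own perspective swaps CD and DC
        for (int k = 0; k < 4; ++k) pb[k] = th[SWAP[k]];
        optimize_gp(st, pb, st.mbar, s);
      }
    } else if (s.kind == 3) {
      double mb = 0;
      for (int j = 0; j < N; ++j)
        if (specs[sp[j]].type_id == s.type_id) mb += 1.0;
      st.mbar = mb;
      if (mb >= N) { st.has_gp = false; return; }
      double pn[4], pm[4];
      for (int k = 0; k < 4; ++k) { pn[k] = st.sn[k]; pm[k] = st.sm[k]; }
      for (int j = 0; j < N; ++j) {
        if (j == i || specs[sp[j]].type_id == s.type_id) continue;
        const OppModel& M = st.mod[j];
        for (int k = 0; k < 4; ++k) { pn[k] += M.n[k]; pm[k] += M.m[k]; }
      }
      double th[4], pb[4];
      for (int k = 0; k < 4; ++k) th[k] = (pm[k] + 1.0) / (pn[k] + 2.0);
      st.has_pooled = true;
      for (int k = 0; k < 4; ++k) st.pooled_th[k] = th[k];
      for (int k = 0; k < 4; ++k) pb[k] = th[SWAP[k]];  // to opponent perspective
      optimize_gp(st, pb, mb, s);
    }
  }

  void optimize_gp(IPState& st, const double pb[4], double mb, const PSpec& s) {
    // unchanged inputs: reuse the cached optimum outright
    if (st.has_prev && st.has_gp && std::fabs(mb - st.last_mbar) < 1e-9) {
      bool same = true;
      for (int k = 0; k < 4; ++k)
        if (std::fabs(pb[k] - st.last_pbar[k]) >= 1e-9) { same = false; break; }
      if (same) return;
    }
    // full multi-start on first use and periodically; tracking mode otherwise
    int mode = 1;
    if (!st.has_prev || st.opt_calls % 50 == 0) mode = 0;
    st.opt_calls += 1;
    gm_optimize(pb, mb, N, Sx, Sy, eps_for(s), st.has_prev ? st.prev : nullptr,
                mode, st.gp);
    for (int k = 0; k < 4; ++k) { st.prev[k] = st.gp[k]; st.last_pbar[k] = pb[k]; }
    st.has_prev = true;
    st.has_gp = true;
    st.last_mbar = mb;
  }

  int move_for(int i, int j) {
    const PSpec& s = specs[sp[i]];
    int lo = out[(size_t)i * N + j];
    switch (s.kind) {
      case 0: {
        double p = (lo < 0) ? (s.fm == 0 ? 1.0 : 0.0) : s.v[lo];
        return rng.move_bern(eff1(p, eps));
      }
      case 1: {
        bool same = specs[sp[j]].type_id == s.type_id;
        const double* v = same ? s.vs : s.vo;
        int fm = same ? s.fm_s : s.fm_o;
        double p = (lo < 0) ? (fm == 0 ? 1.0 : 0.0) : v[lo];
        return rng.move_bern(eff1(p, eps));
      }
      case 3: {
        bool same = specs[sp[j]].type_id == s.type_id;
        double p;
        if (same) p = 1.0;
        else if (lo < 0) p = 1.0;  // cooperative first move
        else p = ip[i].has_gp ? ip[i].gp[lo] : 0.5;
        return rng.move_bern(eff1(p, eps));
      }
      default: {  // ip0
        OppModel& M = ip[i].mod[j];
        int intent;
        if (M.rounds < s.ig_len) {
          intent = infogain_move_c(M.n, M.m, lo, M.hist_mine);
          M.pend_pred = infogain_move_c(M.n2, M.m2, lo < 0 ? -1 : SWAP[lo], M.hist_opp);
        } else {
          M.pend_pred = -1;
          if (M.L > 0) intent = 0;
          else if (lo < 0) intent = 0;
          else intent = rng.move_bern(ip[i].has_gp ? ip[i].gp[lo] : 0.5);
        }
        M.pend_intent = intent;
        return (rng.unif() < eps) ? 1 - intent : intent;
      }
    }
  }

  void observe(int i, int j, int a, int b) {
    const PSpec& s = specs[sp[i]];
    IPState& st = ip[i];
    int prev = out[(size_t)i * N + j];
    if (s.kind == 3) {
      if (specs[sp[j]].type_id == s.type_id) return;
      OppModel& M = st.mod[j];
      if (prev >= 0) { M.n[prev] += 1.0; M.m[prev] += (b == 0); }
      return;
    }
    OppModel& M = st.mod[j];
    double epsA = eps_for(s);
    double theta = gp_theta(st, M, prev);
    double p_gp = (b == 0) ? theta : 1.0 - theta;
    double p_ip;
    if (M.rounds < s.ig_len) {
      bool mism = (b != M.pend_pred);
      if (mism) M.e += 1;
      p_ip = mism ? epsA : 1.0 - epsA;
      // what the opponent would conclude about me
      bool mism2 = (a != M.pend_intent);
      double p_ip2 = mism2 ? epsA : 1.0 - epsA;
      int sprev = prev < 0 ? -1 : SWAP[prev];
      double th2 = (sprev < 0) ? 0.5 : (M.m2[sprev] + 1.0) / (M.n2[sprev] + 2.0);
      double p_gp2 = (a == 0) ? th2 : 1.0 - th2;
      M.L_other += std::log(clamp_prob(p_ip2)) - std::log(clamp_prob(p_gp2));
      if (binom_tail(M.e, M.rounds + 1, epsA) <= s.alpha) M.confident = true;
    } else {
      int sprev = SWAP[prev];
      double gc = st.has_gp ? eff1(st.gp[sprev], epsA) : 0.5;
      double a0 = M.hmm_allc, sw = s.hswitch;
      double apr = a0 * (1.0 - sw) + (1.0 - a0) * sw;
      double eA = (b == 0) ? 1.0 - epsA : epsA;
      double eG = (b == 0) ? gc : 1.0 - gc;
      double marg = apr * eA + (1.0 - apr) * eG;
      M.hmm_allc = (marg > 0) ? apr * eA / marg : apr;
      p_ip = marg;
    }
    M.L += std::log(clamp_prob(p_ip)) - std::log(clamp_prob(p_gp));
    if (prev >= 0) {
      M.n[prev] += 1.0; M.m[prev] += (b == 0);
      int sprev = SWAP[prev];
      M.n2[sprev] += 1.0; M.m2[sprev] += (a == 0);
    }
    if (M.rounds < s.ig_len) {
      M.hist_mine += (a == 0 ? 'C' : 'D'); M.hist_mine += (b == 0 ? 'C' : 'D');
      M.hist_opp += (b == 0 ? 'C' : 'D'); M.hist_opp += (a == 0 ? 'C' : 'D');
    }
    M.rounds += 1;
    if (M.rounds == s.ig_len) M.hmm_allc = sigmoid(M.L_other);
  }

  void play_generation() {
    for (int i = 0; i < N; ++i)
      if (specs[sp[i]].kind >= 2) prepare_slot(i);
    std::fill(fit.begin(), fit.end(), 0.0);
    for (int i = 0; i < N; ++i) {
      for (int j = i + 1; j < N; ++j) {
        int a = move_for(i, j);
        int b = move_for(j, i);
        if (specs[sp[i]].kind >= 2) observe(i, j, a, b);
        if (specs[sp[j]].kind >= 2) observe(j, i, b, a);
        int oi = 2 * a + b, oj = 2 * b + a;
        fit[i] += Sx[oi];
        fit[j] += Sx[oj];
        out[(size_t)i * N + j] = (signed char)oi;
        out[(size_t)j * N + i] = (signed char)oj;
      }
    }
    for (int i = 0; i < N; ++i) fit[i] /= (N - 1);
  }

  int sample_softmax() {
    double fmax = fit[0];
    for (int i = 1; i < N; ++i) fmax = std::max(fmax, fit[i]);
    double tot = 0.0;
    std::vector<double> w(N);
    for (int i = 0; i < N; ++i) { w[i] = std::exp(sigma * (fit[i] - fmax)); tot += w[i]; }
    double u = rng.unif() * tot, acc = 0.0;
    for (int i = 0; i < N; ++i) {
      acc += w[i];
      if (u <= acc) return i;
    }
    return N - 1;
  }

  void update() {
    int dead, model;
    if (rule == 0) { dead = rng.ri(N); model = sample_softmax(); }
    else if (rule == 1) { model = sample_softmax(); dead = rng.ri(N); }
    else {  // Fermi pairwise comparison: adoption is probabilistic
      dead = rng.ri(N);
      model = rng.ri(N);
      double p_adopt = sigmoid(sigma * (fit[model] - fit[dead]));
      if (rng.unif() >= p_adopt) { ++gen; return; }
    }
    int new_spec = sp[model];
    // notify surviving information players of the death and birth
    for (int i = 0; i < N; ++i) {
      if (i == dead) continue;
      const PSpec& s = specs[sp[i]];
      if (s.kind == 2) {
        IPState& st = ip[i];
        OppModel& M = st.mod[dead];
        if (M.L < std::log(s.alpha))
          for (int k = 0; k < 4; ++k) { st.sn[k] += M.n[k]; st.sm[k] += M.m[k]; }
        double mb = 1.0;
        for (int j = 0; j < N; ++j) {
          if (j == i || j == dead) continue;
          mb += sigmoid(st.mod[j].L);
        }
        mb = std::min(std::max(mb, 1.0), (double)N);
        M.reset(std::log(mb / N));
      } else if (s.kind == 3) {
        IPState& st = ip[i];
        if (specs[sp[dead]].type_id != s.type_id) {
          OppModel& M = st.mod[dead];
          for (int k = 0; k < 4; ++k) { st.sn[k] += M.n[k]; st.sm[k] += M.m[k]; }
        }
        st.mod[dead].reset(0.0);
      }
    }
    sp[dead] = new_spec;
    if (specs[new_spec].kind >= 2)
      ip[dead].init(N, std::log(1.0 / N));  // newborn knows only itself
    else
      ip[dead] = IPState();
    for (int j = 0; j < N; ++j) {
      out[(size_t)dead * N + j] = -1;
      out[(size_t)j * N + dead] = -1;
    }
    ++gen;
  }

  int count_type(int type_id) const {
    int c = 0;
    for (int i = 0; i < N; ++i)
      if (specs[sp[i]].type_id == type_id) ++c;
    return c;
  }
};

static std::vector<PSpec> build_specs(const List& spec_list) {
  std::vector<PSpec> specs;
  for (int t = 0; t < spec_list.size(); ++t)
    specs.push_back(parse_spec(as<List>(spec_list[t]), t));
  return specs;
}

// ---------------------------------------------------------------------------
// exported entry points

// [[Rcpp::export]]
int cpp_md5_lsb(std::string s) { return ipdpop_md5::md5_lsb(s); }

// [[Rcpp::export]]
std::string cpp_md5_hex(std::string s) { return ipdpop_md5::md5_hex(s); }

// [[Rcpp::export]]
int cpp_infogain_move(NumericVector n, NumericVector m, int last, std::string hist) {
  double nn[4], mm[4];
  for (int k = 0; k < 4; ++k) { nn[k] = n[k]; mm[k] = m[k]; }
  return infogain_move_c(nn, mm, last, hist);
}

// [[Rcpp::export]]
double cpp_pd_score(NumericVector p, NumericVector q, NumericVector f) {
  double pp[4], qq[4], ff[4];
  for (int k = 0; k < 4; ++k) { pp[k] = p[k]; qq[k] = q[k]; ff[k] = f[k]; }
  return pd_score(pp, qq, ff, 0);
}

// [[Rcpp::export]]
List cpp_groupmax_optimize(NumericVector pbar, double mbar, int N,
                           NumericVector rstp, double eps,
                           Nullable<NumericVector> prev = R_NilValue) {
  double pb[4], Sx[4], Sy[4], outq[4];
  for (int k = 0; k < 4; ++k) pb[k] = pbar[k];
  Sx[0] = rstp[0]; Sx[1] = rstp[1]; Sx[2] = rstp[2]; Sx[3] = rstp[3];
  Sy[0] = rstp[0]; Sy[1] = rstp[2]; Sy[2] = rstp[1]; Sy[3] = rstp[3];
  double pv[4];
  const double* pvp = nullptr;
  if (prev.isNotNull()) {
    NumericVector p0(prev);
    for (int k = 0; k < 4; ++k) pv[k] = p0[k];
    pvp = pv;
  }
  double val = gm_optimize(pb, mbar, N, Sx, Sy, eps, pvp, 0, outq);
  return List::create(_["par"] = NumericVector::create(outq[0], outq[1], outq[2], outq[3]),
                      _["value"] = val);
}

// mean per-round payoffs over a long simulated noisy match
// [[Rcpp::export]]
NumericVector cpp_sim_match(NumericVector p, NumericVector q, double eps,
                            int rounds, NumericVector rstp, double seed,
                            std::string fm_p = "C", std::string fm_q = "C") {
  RNG rng(stream_seed(seed, 0));
  double pe[4], qe[4];
  double pp[4], qq[4];
  for (int k = 0; k < 4; ++k) { pp[k] = p[k]; qq[k] = q[k]; }
  eff4(pp, eps, pe);
  eff4(qq, eps, qe);
  double Sx[4] = {rstp[0], rstp[1], rstp[2], rstp[3]};
  double Sy[4] = {rstp[0], rstp[2], rstp[1], rstp[3]};
  int a = rng.move_bern(eff1(fm_p == "C" ? 1.0 : 0.0, eps));
  int b = rng.move_bern(eff1(fm_q == "C" ? 1.0 : 0.0, eps));
  double accp = 0.0, accq = 0.0;
  int o = 2 * a + b;
  accp += Sx[o]; accq += Sy[o];
  for (int t = 1; t < rounds; ++t) {
    a = rng.move_bern(pe[o]);
    b = rng.move_bern(qe[SWAP[o]]);
    o = 2 * a + b;
    accp += Sx[o]; accq += Sy[o];
  }
  return NumericVector::create(accp / rounds, accq / rounds);
}

// infogain identification: one IP0 vs one opponent for `rounds` rounds,
// returning the mismatch count between the opponent's observed moves and
// the infogain moves an IP0 twin would have played. opp_is_ip: the opponent
// is a second IP0 (negative class).
static int infogain_duel_c(const double qv[4], int fm_q, bool opp_is_ip,
                           int rounds, double eps, RNG& rng,
                           std::vector<int>* trace_pred = nullptr,
                           std::vector<int>* trace_a = nullptr,
                           std::vector<int>* trace_b = nullptr) {
  double nX[4] = {0, 0, 0, 0}, mX[4] = {0, 0, 0, 0};
  double n2[4] = {0, 0, 0, 0}, m2[4] = {0, 0, 0, 0};
  std::string histX, histY;
  int outX = -1;
  int e = 0;
  for (int t = 0; t < rounds; ++t) {
    int pred = infogain_move_c(n2, m2, outX < 0 ? -1 : SWAP[outX], histY);
    int intent = infogain_move_c(nX, mX, outX, histX);
    int a = (rng.unif() < eps) ? 1 - intent : intent;
    int b;
    if (opp_is_ip) {
      b = (rng.unif() < eps) ? 1 - pred : pred;
    } else {
      double pc = (outX < 0) ? (fm_q == 0 ? 1.0 : 0.0) : qv[SWAP[outX]];
      b = rng.move_bern(eff1(pc, eps));
    }
    if (b != pred) ++e;
    if (outX >= 0) {
      nX[outX] += 1.0; mX[outX] += (b == 0);
      int s = SWAP[outX];
      n2[s] += 1.0; m2[s] += (a == 0);
    }
    histX += (a == 0 ? 'C' : 'D'); histX += (b == 0 ? 'C' : 'D');
    histY += (b == 0 ? 'C' : 'D'); histY += (a == 0 ? 'C' : 'D');
    outX = 2 * a + b;
    if (trace_pred) { trace_pred->push_back(pred); trace_a->push_back(a); trace_b->push_back(b); }
  }
  return e;
}

// [[Rcpp::export]]
IntegerVector cpp_infogain_batch(NumericVector q, std::string first_move,
                                 bool opp_is_ip, int rounds, double eps,
                                 int n_rep, double seed) {
  double qv[4] = {0.5, 0.5, 0.5, 0.5};
  if (q.size() == 4)
    for (int k = 0; k < 4; ++k) qv[k] = q[k];
  int fm = (first_move == "D") ? 1 : 0;
  IntegerVector out(n_rep);
  for (int r = 0; r < n_rep; ++r) {
    RNG rng(stream_seed(seed, r));
    out[r] = infogain_duel_c(qv, fm, opp_is_ip, rounds, eps, rng);
    if (r % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// [[Rcpp::export]]
DataFrame cpp_infogain_trace(NumericVector q, std::string first_move,
                             bool opp_is_ip, int rounds, double eps, double seed) {
  double qv[4] = {0.5, 0.5, 0.5, 0.5};
  if (q.size() == 4)
    for (int k = 0; k < 4; ++k) qv[k] = q[k];
  int fm = (first_move == "D") ? 1 : 0;
  RNG rng(stream_seed(seed, 0));
  std::vector<int> pred, a, b;
  infogain_duel_c(qv, fm, opp_is_ip, rounds, eps, rng, &pred, &a, &b);
  return DataFrame::create(_["round"] = seq_len(rounds), _["predicted"] = pred,
                           _["my_move"] = a, _["opp_move"] = b);
}

// [[Rcpp::export]]
List cpp_run_fixation_batch(List spec_list, int m0, int N, NumericVector rstp,
                            double eps, double sigma, std::string rule,
                            int n_sims, double seed, int max_gen) {
  std::vector<PSpec> specs = build_specs(spec_list);
  if (specs.size() != 2) stop("fixation runs need exactly two player specs");
  int rl = (rule == "moran") ? 1 : (rule == "fermi" ? 2 : 0);
  double RSTP[4] = {rstp[0], rstp[1], rstp[2], rstp[3]};
  IntegerVector fixed(n_sims), gens(n_sims);
  std::vector<int> assign(N);
  for (int i = 0; i < N; ++i) assign[i] = (i < m0) ? 0 : 1;
  for (int s = 0; s < n_sims; ++s) {
    Engine eng(specs, assign, RSTP, eps, sigma, rl, stream_seed(seed, s));
    int res = NA_INTEGER;
    while (eng.gen < max_gen) {
      eng.play_generation();
      eng.update();
      int c = eng.count_type(0);
      if (c == 0) { res = 0; break; }
      if (c == eng.N) { res = 1; break; }
    }
    fixed[s] = res;
    gens[s] = eng.gen;
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["fixed"] = fixed, _["generations"] = gens);
}

// [[Rcpp::export]]
List cpp_simulate_population(List spec_list, IntegerVector counts, int generations,
                             NumericVector rstp, double eps, double sigma,
                             std::string rule, bool do_update, double seed) {
  std::vector<PSpec> specs = build_specs(spec_list);
  int ntype = specs.size();
  if (counts.size() != ntype) stop("counts must match the number of specs");
  std::vector<int> assign;
  for (int t = 0; t < ntype; ++t)
    for (int k = 0; k < counts[t]; ++k) assign.push_back(t);
  int N = (int)assign.size();
  double RSTP[4] = {rstp[0], rstp[1], rstp[2], rstp[3]};
  int rl = (rule == "moran") ? 1 : (rule == "fermi" ? 2 : 0);
  Engine eng(specs, assign, RSTP, eps, sigma, rl, stream_seed(seed, 0));

  IntegerMatrix type_counts(generations, ntype);
  NumericMatrix mean_fit(generations, ntype);
  NumericMatrix outcome_freq(generations, 4);
  NumericMatrix slot_fit(generations == 0 ? 0 : 1, N);
  for (int g = 0; g < generations; ++g) {
    eng.play_generation();
    std::vector<double> ftot(ntype, 0.0);
    std::vector<int> fcnt(ntype, 0);
    for (int i = 0; i < eng.N; ++i) {
      int t = eng.sp[i];
      ftot[t] += eng.fit[i];
      fcnt[t] += 1;
    }
    for (int t = 0; t < ntype; ++t) {
      type_counts(g, t) = fcnt[t];
      mean_fit(g, t) = fcnt[t] ? ftot[t] / fcnt[t] : NA_REAL;
    }
    double oc[4] = {0, 0, 0, 0};
    for (int i = 0; i < eng.N; ++i)
      for (int j = 0; j < eng.N; ++j) {
        if (i == j) continue;
        int o = eng.out[(size_t)i * eng.N + j];
        if (o >= 0) oc[o] += 1.0;
      }
    double tot = oc[0] + oc[1] + oc[2] + oc[3];
    for (int k = 0; k < 4; ++k) outcome_freq(g, k) = tot > 0 ? oc[k] / tot : NA_REAL;
    if (g == generations - 1)
      for (int i = 0; i < eng.N; ++i) slot_fit(0, i) = eng.fit[i];
    if (do_update) eng.update();
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["type_counts"] = type_counts, _["mean_fitness"] = mean_fit,
                      _["outcome_freq"] = outcome_freq, _["last_fitness"] = slot_fit);
}
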
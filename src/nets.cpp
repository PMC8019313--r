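// Recurrent architectures for the role-filler binding task.
//
// Four architectures (layer-normalized RNN, layer-normalized LSTM, Fast
// Weights, Differentiable Neural Computer) share one contract: a story is a
// sequence of token indices into a fixed embedding matrix, fed one token
// per step; the prediction is a linear readout of the final hidden state
// (for the DNC, of hidden state and read vector). Training minimizes
// 0.5 * ||prediction - target embedding||^2 with Adam. Backpropagation
// through time is hand-derived here and verified in the test suite by
// finite differences and by a pure-R reference forward pass.

#include <RcppArmadillo.h>
#include <map>
#include <string>
#include <vector>

// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

typedef std::map<std::string, mat> Params;

static const double LN_EPS = 1e-5;
static const double COS_EPS = 1e-8;

static Params as_params(const Rcpp::List& lst) {
  Params p;
  Rcpp::CharacterVector nm = lst.names();
  for (int i = 0; i < lst.size(); ++i) {
    p[Rcpp::as<std::string>(nm[i])] = Rcpp::as<mat>(lst[i]);
  }
  return p;
}

static Rcpp::List as_list(const Params& p) {
  Rcpp::List out;
  for (Params::const_iterator it = p.begin(); it != p.end(); ++it) {
    out[it->first] = it->second;
  }
  return out;
}

static Params zeros_like(const Params& p) {
  Params g;
  for (Params::const_iterator it = p.begin(); it != p.end(); ++it) {
    g[it->first] = zeros<mat>(it->second.n_rows, it->second.n_cols);
  }
  return g;
}

// ---------------------------------------------------------------------------
// Layer normalization over rows of a batch matrix, with learnable gain/bias.

struct LNCache {
  mat zhat;   // (z - mu) / sqrt(var + eps)
  vec inv;    // 1 / sqrt(var + eps), per row
};

static mat ln_forward(const mat& Z, const vec& g, const vec& b, LNCache& c) {
  vec mu = mean(Z, 1);
  mat Zc = Z.each_col() - mu;
  vec v = mean(square(Zc), 1);
  c.inv = 1.0 / sqrt(v + LN_EPS);
  c.zhat = Zc.each_col() % c.inv;
  mat out = c.zhat.each_row() % g.t();
  out.each_row() += b.t();
  return out;
}

// dOut -> dZ; accumulates dg, db.
static mat ln_backward(const mat& dOut, const vec& g, const LNCache& c,
                       mat& dg, mat& db) {
  dg += sum(dOut % c.zhat, 0).t();
  db += sum(dOut, 0).t();
  mat dzh = dOut.each_row() % g.t();
  vec m1 = mean(dzh, 1);
  vec m2 = mean(dzh % c.zhat, 1);
  mat dZ = dzh;
  dZ.each_col() -= m1;
  dZ -= c.zhat.each_col() % m2;
  dZ.each_col() %= c.inv;
  return dZ;
}

static mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// ---------------------------------------------------------------------------
// Embedding lookup: rows of E for one timestep across the batch.

static mat embed(const imat& X, const mat& E, int t) {
  mat out(X.n_rows, E.n_cols);
  for (uword b = 0; b < X.n_rows; ++b) out.row(b) = E.row(X(b, t));
  return out;
}

// ===========================================================================
// RNN: h <- tanh(LN(W h + U x))

struct RnnCache {
  std::vector<mat> X, H;        // H[t+1] is state after step t; H[0] = 0
  std::vector<LNCache> ln;
};

static mat rnn_forward(const Params& p, const imat& X, const mat& E,
                       RnnCache& c) {
  const mat& W = p.at("W");
  const mat& U = p.at("U");
  int B = X.n_rows, L = X.n_cols, n = W.n_rows;
  c.X.resize(L); c.H.resize(L + 1); c.ln.resize(L);
  c.H[0] = zeros<mat>(B, n);
  for (int t = 0; t < L; ++t) {
    c.X[t] = embed(X, E, t);
    mat Z = c.H[t] * W.t() + c.X[t] * U.t();
    mat A = ln_forward(Z, p.at("g"), p.at("b"), c.ln[t]);
    c.H[t + 1] = tanh(A);
  }
  mat pred = c.H[L] * p.at("Wo").t();
  pred.each_row() += p.at("bo").t();
  return pred;
}

static void rnn_backward(const Params& p, const RnnCache& c, const mat& dPred,
                         Params& g) {
  const mat& W = p.at("W");
  int L = c.X.size();
  g["Wo"] += dPred.t() * c.H[L];
  g["bo"] += sum(dPred, 0).t();
  mat dH = dPred * p.at("Wo");
  for (int t = L - 1; t >= 0; --t) {
    mat dA = dH % (1.0 - square(c.H[t + 1]));
    mat dZ = ln_backward(dA, p.at("g").col(0), c.ln[t], g["g"], g["b"]);
    g["W"] += dZ.t() * c.H[t];
    g["U"] += dZ.t() * c.X[t];
    dH = dZ * W;
  }
}

// ===========================================================================
// LSTM with per-gate layer normalization:
//   z = Wx x + Wh h;  i,f = sigm(LN(.)), g~ = tanh(LN(.)), o = sigm(LN(.))
//   c <- f*c + i*g~;  h <- o * tanh(LN_c(c))

struct LstmCache {
  std::vector<mat> X, H, C;              // H[0] = C[0] = 0
  std::vector<mat> gi, gf, gg, go, tc;   // gate activations, tanh(LN(c))
  std::vector<LNCache> li, lf, lg, lo, lc;
};

static mat lstm_forward(const Params& p, const imat& X, const mat& E,
                        LstmCache& c) {
  const mat& Wx = p.at("Wx");
  const mat& Wh = p.at("Wh");
  int B = X.n_rows, L = X.n_cols, n = Wh.n_cols;
  c.X.resize(L); c.H.resize(L + 1); c.C.resize(L + 1);
  c.gi.resize(L); c.gf.resize(L); c.gg.resize(L); c.go.resize(L); c.tc.resize(L);
  c.li.resize(L); c.lf.resize(L); c.lg.resize(L); c.lo.resize(L); c.lc.resize(L);
  c.H[0] = zeros<mat>(B, n);
  c.C[0] = zeros<mat>(B, n);
  for (int t = 0; t < L; ++t) {
    c.X[t] = embed(X, E, t);
    mat Z = c.X[t] * Wx.t() + c.H[t] * Wh.t();
    c.gi[t] = sigm(ln_forward(Z.cols(0, n - 1), p.at("g_i"), p.at("b_i"), c.li[t]));
    c.gf[t] = sigm(ln_forward(Z.cols(n, 2 * n - 1), p.at("g_f"), p.at("b_f"), c.lf[t]));
    c.gg[t] = tanh(ln_forward(Z.cols(2 * n, 3 * n - 1), p.at("g_g"), p.at("b_g"), c.lg[t]));
    c.go[t] = sigm(ln_forward(Z.cols(3 * n, 4 * n - 1), p.at("g_o"), p.at("b_o"), c.lo[t]));
    c.C[t + 1] = c.gf[t] % c.C[t] + c.gi[t] % c.gg[t];
    c.tc[t] = tanh(ln_forward(c.C[t + 1], p.at("g_c"), p.at("b_c"), c.lc[t]));
    c.H[t + 1] = c.go[t] % c.tc[t];
  }
  mat pred = c.H[L] * p.at("Wo").t();
  pred.each_row() += p.at("bo").t();
  return pred;
}

static void lstm_backward(const Params& p, const LstmCache& c, const mat& dPred,
                          Params& g) {
  const mat& Wx = p.at("Wx");
  const mat& Wh = p.at("Wh");
  int L = c.X.size(), n = Wh.n_cols;
  g["Wo"] += dPred.t() * c.H[L];
  g["bo"] += sum(dPred, 0).t();
  mat dH = dPred * p.at("Wo");
  mat dC = zeros<mat>(dH.n_rows, n);
  for (int t = L - 1; t >= 0; --t) {
    mat dgo = dH % c.tc[t];
    mat dtc = dH % c.go[t];
    mat dlnc = dtc % (1.0 - square(c.tc[t]));
    dC += ln_backward(dlnc, p.at("g_c").col(0), c.lc[t], g["g_c"], g["b_c"]);
    mat dgi = dC % c.gg[t];
    mat dgg = dC % c.gi[t];
    mat dgf = dC % c.C[t];
    mat dCprev = dC % c.gf[t];
    mat dZ(dH.n_rows, 4 * n);
    dZ.cols(0, n - 1) = ln_backward(dgi % c.gi[t] % (1.0 - c.gi[t]),
                                    p.at("g_i").col(0), c.li[t], g["g_i"], g["b_i"]);
    dZ.cols(n, 2 * n - 1) = ln_backward(dgf % c.gf[t] % (1.0 - c.gf[t]),
                                        p.at("g_f").col(0), c.lf[t], g["g_f"], g["b_f"]);
    dZ.cols(2 * n, 3 * n - 1) = ln_backward(dgg % (1.0 - square(c.gg[t])),
                                            p.at("g_g").col(0), c.lg[t], g["g_g"], g["b_g"]);
    dZ.cols(3 * n, 4 * n - 1) = ln_backward(dgo % c.go[t] % (1.0 - c.go[t]),
                                            p.at("g_o").col(0), c.lo[t], g["g_o"], g["b_o"]);
    g["Wx"] += dZ.t() * c.X[t];
    g["Wh"] += dZ.t() * c.H[t];
    dH = dZ * Wh;
    dC = dCprev;
  }
}

// ===========================================================================
// Fast Weights: A <- lambda A + eta h h^T (with the incoming hidden state),
// then settle: h0 = tanh(z), h_s = tanh(LN(z + A h_{s-1})), z = W h + U x + b0.

// The fast-weight matrix A_t = eta * sum_{j<=t} lambda^(t-j) h_j h_j^T is a
// decaying sum of outer products of past hidden states, so products A_t v
// are computed in attention form over the stored history (O(t n) instead of
// O(n^2)); A is symmetric by construction and never materialized during
// training.
struct FwCache {
  std::vector<mat> X, H, Z;                    // H[0] = 0
  std::vector<std::vector<mat> > HS;           // settling iterates, HS[t][0] = h0
  std::vector<std::vector<LNCache> > ln;       // per settling iteration
};

// Batched attention-form product with the fast-weight matrix: for every
// batch row simultaneously, A_(t) V = eta * sum_{j=1..t} lambda^(t-j)
// h_j (h_j . v). A is symmetric, so the same routine serves forward and
// backward products. All operations are whole-matrix (B x n) elementwise.
static mat fw_A_times_batch(const std::vector<mat>& H, int t, double lambda,
                            double eta, const mat& V) {
  mat out(V.n_rows, V.n_cols, fill::zeros);
  double w = eta;
  for (int j = t; j >= 1; --j) {     // w = eta * lambda^(t-j)
    vec d = w * sum(H[j] % V, 1);
    out += H[j].each_col() % d;
    w *= lambda;
  }
  return out;
}

static mat fw_act(const mat& x, bool relu) {
  return relu ? mat(clamp(x, 0.0, datum::inf)) : mat(tanh(x));
}

// derivative of the activation given its output
static mat fw_act_d(const mat& y, bool relu) {
  return relu ? mat(conv_to<mat>::from(y > 0.0)) : mat(1.0 - square(y));
}

static mat fw_forward(const Params& p, const imat& X, const mat& E,
                      double lambda, double eta, int S, bool relu, FwCache& c) {
  const mat& W = p.at("W");
  const mat& U = p.at("U");
  int B = X.n_rows, L = X.n_cols, n = W.n_rows;
  c.X.resize(L); c.H.resize(L + 1); c.Z.resize(L);
  c.HS.resize(L); c.ln.resize(L);
  c.H[0] = zeros<mat>(B, n);
  for (int t = 0; t < L; ++t) {
    c.X[t] = embed(X, E, t);
    c.Z[t] = c.H[t] * W.t() + c.X[t] * U.t();
    c.Z[t].each_row() += p.at("b0").t();
    c.HS[t].resize(S + 1);
    c.ln[t].resize(S);
    c.HS[t][0] = fw_act(c.Z[t], relu);
    for (int s = 0; s < S; ++s) {
      mat pre = c.Z[t] + fw_A_times_batch(c.H, t, lambda, eta, c.HS[t][s]);
      c.HS[t][s + 1] = fw_act(ln_forward(pre, p.at("g"), p.at("b"), c.ln[t][s]), relu);
    }
    c.H[t + 1] = c.HS[t][S];
  }
  mat pred = c.H[L] * p.at("Wo").t();
  pred.each_row() += p.at("bo").t();
  return pred;
}

static void fw_backward(const Params& p, const FwCache& c, const mat& dPred,
                        double lambda, double eta, int S, bool relu, Params& g) {
  const mat& W = p.at("W");
  int L = c.X.size(), n = W.n_rows, B = dPred.n_rows;
  g["Wo"] += dPred.t() * c.H[L];
  g["bo"] += sum(dPred, 0).t();
  mat dH = dPred * p.at("Wo");
  // dHbuf[j]: accumulated gradient on c.H[j] from fast-weight reads at
  // steps >= j (each step's dA is rank 1, so its pullback is O(t n))
  std::vector<mat> dHbuf(L + 1, zeros<mat>(B, n));
  for (int t = L - 1; t >= 0; --t) {
    dH += dHbuf[t + 1];
    mat dZ = zeros<mat>(B, n);
    mat dhs = dH;  // gradient w.r.t. HS[t][S]
    for (int s = S - 1; s >= 0; --s) {
      mat dln = dhs % fw_act_d(c.HS[t][s + 1], relu);
      mat dpre = ln_backward(dln, p.at("g").col(0), c.ln[t][s], g["g"], g["b"]);
      dZ += dpre;
      dhs = fw_A_times_batch(c.H, t, lambda, eta, dpre);  // A symmetric
      // per-step dA is rank 1 (dpre^T h0) per batch row:
      // dH_j += eta lam^(t-j) [dpre (h0 . H_j) + h0 (dpre . H_j)]
      const mat& h0 = c.HS[t][s];
      double w = eta;
      for (int j = t; j >= 1; --j) {
        vec dh = w * sum(c.H[j] % h0, 1);
        vec dd = w * sum(c.H[j] % dpre, 1);
        dHbuf[j] += (dpre.each_col() % dh) + (h0.each_col() % dd);
        w *= lambda;
      }
    }
    dZ += dhs % fw_act_d(c.HS[t][0], relu);  // h0 = act(z)
    g["W"] += dZ.t() * c.H[t];
    g["U"] += dZ.t() * c.X[t];
    g["b0"] += sum(dZ, 0).t();
    dH = dZ * W;
  }
}

// ===========================================================================
// DNC: LSTM controller + external memory with content-based addressing,
// dynamic allocation, and temporal linkage (one write head, one read head).

struct DncStep {
  vec in;                        // [x; r_prev]
  vec i, f, gc, o, ccell, tc, h; // controller gate activations and states
  vec xi;
  vec kr, kw, e, v;              // parsed interface (post-activation)
  double br, bw, fr, ga, gw;     // strengths and gates
  vec pi;                        // read modes (softmax)
  vec psi, u, alloc, csw, cw, ww, p, fvec, bvec, csr, cr, wr, r;
  uvec phi;                      // usage sort order (ascending)
  mat M, Lm;
};

struct DncCache {
  std::vector<DncStep> steps;
};

struct DncDims { int n, d, N, W; };

static double softplus(double x) {
  return x > 30.0 ? x : std::log1p(std::exp(x));
}

static vec softmax(const vec& x) {
  vec e = exp(x - x.max());
  return e / accu(e);
}

// cosine similarity of each memory row with key k
static vec content_scores(const mat& M, const vec& k) {
  vec nk(1); nk(0) = norm(k);
  vec s(M.n_rows);
  for (uword i = 0; i < M.n_rows; ++i) {
    s(i) = dot(M.row(i), k) / (norm(M.row(i)) * nk(0) + COS_EPS);
  }
  return s;
}

// backward of content_scores: accumulate dM, dk given dcs
static void content_scores_bwd(const mat& M, const vec& k, const vec& cs,
                               const vec& dcs, mat& dM, vec& dk) {
  double nk = norm(k);
  for (uword i = 0; i < M.n_rows; ++i) {
    rowvec mi = M.row(i);
    double ni = norm(mi);
    double den = ni * nk + COS_EPS;
    rowvec dmi = k.t() / den;
    if (ni > 1e-12) dmi -= cs(i) * nk / (ni * den) * mi;
    dM.row(i) += dcs(i) * dmi;
    vec dki = mi.t() / den;
    if (nk > 1e-12) dki -= cs(i) * ni / (nk * den) * k;
    dk += dcs(i) * dki;
  }
}

static uvec stable_ascending(const vec& u) {
  std::vector<uword> idx(u.n_elem);
  for (uword i = 0; i < u.n_elem; ++i) idx[i] = i;
  std::stable_sort(idx.begin(), idx.end(),
                   [&u](uword a, uword b) { return u(a) < u(b); });
  return uvec(idx);
}

static vec dnc_forward_seq(const Params& p, const ivec& tokens, const mat& E,
                           const DncDims& dm, DncCache& cache) {
  int L = tokens.n_elem, n = dm.n, N = dm.N, W = dm.W;
  cache.steps.resize(L);
  vec h = zeros<vec>(n), ccell = zeros<vec>(n), r = zeros<vec>(W);
  vec u = zeros<vec>(N), pvec = zeros<vec>(N), wr = zeros<vec>(N), ww = zeros<vec>(N);
  mat M = zeros<mat>(N, W), Lm = zeros<mat>(N, N);
  const mat& Wx = p.at("Wx");
  const mat& Wh = p.at("Wh");
  for (int t = 0; t < L; ++t) {
    DncStep& st = cache.steps[t];
    st.in = join_cols(E.row(tokens(t)).t(), r);
    vec z = Wx * st.in + Wh * h + p.at("bg").col(0);
    st.i = 1.0 / (1.0 + exp(-z.subvec(0, n - 1)));
    st.f = 1.0 / (1.0 + exp(-z.subvec(n, 2 * n - 1)));
    st.gc = tanh(z.subvec(2 * n, 3 * n - 1));
    st.o = 1.0 / (1.0 + exp(-z.subvec(3 * n, 4 * n - 1)));
    st.ccell = st.f % ccell + st.i % st.gc;
    st.tc = tanh(st.ccell);
    st.h = st.o % st.tc;
    st.xi = p.at("Wi") * st.h + p.at("bi").col(0);
    // parse interface: kr(W), br, kw(W), bw, e(W), v(W), free, ga, gw, pi(3)
    int q = 0;
    st.kr = st.xi.subvec(q, q + W - 1); q += W;
    st.br = 1.0 + softplus(st.xi(q)); q += 1;
    st.kw = st.xi.subvec(q, q + W - 1); q += W;
    st.bw = 1.0 + softplus(st.xi(q)); q += 1;
    st.e = 1.0 / (1.0 + exp(-st.xi.subvec(q, q + W - 1))); q += W;
    st.v = st.xi.subvec(q, q + W - 1); q += W;
    st.fr = 1.0 / (1.0 + std::exp(-st.xi(q))); q += 1;
    st.ga = 1.0 / (1.0 + std::exp(-st.xi(q))); q += 1;
    st.gw = 1.0 / (1.0 + std::exp(-st.xi(q))); q += 1;
    st.pi = softmax(st.xi.subvec(q, q + 2));
    // usage and allocation
    st.psi = 1.0 - st.fr * wr;
    st.u = (u + ww - u % ww) % st.psi;
    st.phi = stable_ascending(st.u);
    st.alloc = zeros<vec>(N);
    double run = 1.0;
    for (int j = 0; j < N; ++j) {
      st.alloc(st.phi(j)) = (1.0 - st.u(st.phi(j))) * run;
      run *= st.u(st.phi(j));
    }
    // write weighting
    st.csw = content_scores(M, st.kw);
    st.cw = softmax(st.bw * st.csw);
    st.ww = st.gw * (st.ga * st.alloc + (1.0 - st.ga) * st.cw);
    // memory update
    st.M = M % (1.0 - st.ww * st.e.t()) + st.ww * st.v.t();
    // temporal linkage
    st.Lm = Lm;
    for (int i = 0; i < N; ++i) {
      for (int j = 0; j < N; ++j) {
        st.Lm(i, j) = (1.0 - st.ww(i) - st.ww(j)) * Lm(i, j) + st.ww(i) * pvec(j);
      }
      st.Lm(i, i) = 0.0;
    }
    st.p = (1.0 - accu(st.ww)) * pvec + st.ww;
    // read weighting
    st.fvec = st.Lm * wr;
    st.bvec = st.Lm.t() * wr;
    st.csr = content_scores(st.M, st.kr);
    st.cr = softmax(st.br * st.csr);
    st.wr = st.pi(0) * st.bvec + st.pi(1) * st.cr + st.pi(2) * st.fvec;
    st.r = st.M.t() * st.wr;
    // roll state
    h = st.h; ccell = st.ccell; r = st.r;
    u = st.u; pvec = st.p; wr = st.wr; ww = st.ww;
    M = st.M; Lm = st.Lm;
  }
  return p.at("Wy") * h + p.at("Wr") * r + p.at("by").col(0);
}

static void dnc_backward_seq(const Params& p, const ivec& tokens,
                             const DncCache& cache, const vec& dPred,
                             const DncDims& dm, Params& g) {
  int L = tokens.n_elem, n = dm.n, N = dm.N, W = dm.W;
  const DncStep& last = cache.steps[L - 1];
  g["Wy"] += dPred * last.h.t();
  g["Wr"] += dPred * last.r.t();
  g["by"] += dPred;
  vec dh = p.at("Wy").t() * dPred;
  vec dr = p.at("Wr").t() * dPred;
  vec dc = zeros<vec>(n);
  vec du = zeros<vec>(N), dpv = zeros<vec>(N), dwr = zeros<vec>(N), dww = zeros<vec>(N);
  mat dM = zeros<mat>(N, W), dLm = zeros<mat>(N, N);
  for (int t = L - 1; t >= 0; --t) {
    const DncStep& st = cache.steps[t];
    // previous-step state values
    vec h_prev = t > 0 ? cache.steps[t - 1].h : zeros<vec>(n);
    vec c_prev = t > 0 ? cache.steps[t - 1].ccell : zeros<vec>(n);
    vec u_prev = t > 0 ? cache.steps[t - 1].u : zeros<vec>(N);
    vec p_prev = t > 0 ? cache.steps[t - 1].p : zeros<vec>(N);
    vec wr_prev = t > 0 ? cache.steps[t - 1].wr : zeros<vec>(N);
    vec ww_prev = t > 0 ? cache.steps[t - 1].ww : zeros<vec>(N);
    mat M_prev = t > 0 ? cache.steps[t - 1].M : zeros<mat>(N, W);
    mat L_prev = t > 0 ? cache.steps[t - 1].Lm : zeros<mat>(N, N);

    vec dxi = zeros<vec>(st.xi.n_elem);
    vec dwr_prev = zeros<vec>(N), dww_prev = zeros<vec>(N);
    vec du_prev = zeros<vec>(N), dp_prev = zeros<vec>(N);
    mat dM_prev = zeros<mat>(N, W), dL_prev = zeros<mat>(N, N);

    // --- read vector r = M^T wr
    dM += st.wr * dr.t();
    dwr += st.M * dr;
    // --- wr = pi0 b + pi1 cr + pi2 f
    vec dpi = zeros<vec>(3);
    dpi(0) = dot(dwr, st.bvec);
    dpi(1) = dot(dwr, st.cr);
    dpi(2) = dot(dwr, st.fvec);
    vec dbv = st.pi(0) * dwr;
    vec dcr = st.pi(1) * dwr;
    vec dfv = st.pi(2) * dwr;
    // --- read content cr = softmax(br * csr) over updated M
    // softmax backward: ds = y % (dy - dot(dy, y)); chain into beta and key
    {
      vec ds = st.cr % (dcr - dot(dcr, st.cr));
      double dbr = dot(ds, st.csr);
      vec dcs = st.br * ds;
      vec dkr = zeros<vec>(W);
      content_scores_bwd(st.M, st.kr, st.csr, dcs, dM, dkr);
      dxi.subvec(0, W - 1) += dkr;
      // beta = 1 + softplus(xi); d beta / d xi = sigmoid(xi)
      dxi(W) += dbr / (1.0 + std::exp(-st.xi(W)));
    }
    // --- forward/backward read vectors from linkage
    dLm += dfv * wr_prev.t();
    dwr_prev += st.Lm.t() * dfv;
    dLm += wr_prev * dbv.t();
    dwr_prev += st.Lm * dbv;
    // --- precedence p = (1 - sum(ww)) p_prev + ww
    dww += dpv - dot(dpv, p_prev);
    dp_prev += (1.0 - accu(st.ww)) * dpv;
    // --- linkage update (diag of L forced to zero)
    dLm.diag().zeros();
    for (int i = 0; i < N; ++i) {
      for (int j = 0; j < N; ++j) {
        if (i == j) continue;
        double d = dLm(i, j);
        if (d == 0.0) continue;
        dL_prev(i, j) += (1.0 - st.ww(i) - st.ww(j)) * d;
        dww(i) += d * (p_prev(j) - L_prev(i, j));
        dww(j) += -d * L_prev(i, j);
        dp_prev(j) += d * st.ww(i);
      }
    }
    // --- memory update M = M_prev % (1 - ww e^T) + ww v^T
    vec de = zeros<vec>(W), dv = zeros<vec>(W);
    for (int i = 0; i < N; ++i) {
      for (int j = 0; j < W; ++j) {
        double d = dM(i, j);
        dM_prev(i, j) += d * (1.0 - st.ww(i) * st.e(j));
        dww(i) += d * (st.v(j) - M_prev(i, j) * st.e(j));
        de(j) += -d * M_prev(i, j) * st.ww(i);
        dv(j) += d * st.ww(i);
      }
    }
    {
      int q = 2 * W + 2;
      dxi.subvec(q, q + W - 1) += de % st.e % (1.0 - st.e);
      dxi.subvec(q + W, q + 2 * W - 1) += dv;
    }
    // --- write weighting ww = gw (ga a + (1-ga) cw)
    vec mix = st.ga * st.alloc + (1.0 - st.ga) * st.cw;
    double dgw = dot(dww, mix);
    vec dmix = st.gw * dww;
    double dga = dot(dmix, st.alloc - st.cw);
    vec dalloc = st.ga * dmix;
    vec dcw = (1.0 - st.ga) * dmix;
    // write content cw = softmax(bw * csw) over M_prev
    {
      vec ds = st.cw % (dcw - dot(dcw, st.cw));
      double dbw = dot(ds, st.csw);
      vec dcs = st.bw * ds;
      vec dkw = zeros<vec>(W);
      content_scores_bwd(M_prev, st.kw, st.csw, dcs, dM_prev, dkw);
      int q = W + 1;
      dxi.subvec(q, q + W - 1) += dkw;
      dxi(q + W) += dbw / (1.0 + std::exp(-st.xi(q + W)));
    }
    // allocation backward: a(phi_j) = (1 - u(phi_j)) * prod_{i<j} u(phi_i)
    {
      // prefix products over sorted usage
      std::vector<double> pre(N + 1, 1.0);
      for (int j = 0; j < N; ++j) pre[j + 1] = pre[j] * st.u(st.phi(j));
      for (int k = 0; k < N; ++k) {
        double dak = dalloc(st.phi(k));
        if (dak == 0.0) continue;
        du(st.phi(k)) += -dak * pre[k];
        double run = 1.0;  // prod of s_{j+1..k-1}
        for (int j = k - 1; j >= 0; --j) {
          du(st.phi(j)) += dak * (1.0 - st.u(st.phi(k))) * pre[j] * run;
          run *= st.u(st.phi(j));
          if (run == 0.0) break;  // every remaining term carries this factor
        }
      }
    }
    // --- usage u = (u_prev + ww_prev - u_prev % ww_prev) % psi
    vec base = u_prev + ww_prev - u_prev % ww_prev;
    vec dbase = du % st.psi;
    vec dpsi = du % base;
    double dfr = -dot(dpsi, wr_prev);
    dwr_prev += -st.fr * dpsi;
    du_prev += dbase % (1.0 - ww_prev);
    dww_prev += dbase % (1.0 - u_prev);
    {
      int q = 4 * W + 2;
      dxi(q) += dfr * st.fr * (1.0 - st.fr);
      double dga_x = dga * st.ga * (1.0 - st.ga);
      dxi(q + 1) += dga_x;
      dxi(q + 2) += dgw * st.gw * (1.0 - st.gw);
      // read modes pi = softmax(xi_pi)
      vec dspi = st.pi % (dpi - dot(dpi, st.pi));
      dxi.subvec(q + 3, q + 5) += dspi;
    }
    // --- interface xi = Wi h + bi
    g["Wi"] += dxi * st.h.t();
    g["bi"] += dxi;
    dh += p.at("Wi").t() * dxi;
    // --- controller LSTM
    vec do_ = dh % st.tc;
    dc += dh % st.o % (1.0 - square(st.tc));
    vec di = dc % st.gc;
    vec dgc = dc % st.i;
    vec df = dc % c_prev;
    vec dc_prev = dc % st.f;
    vec dz(4 * n);
    dz.subvec(0, n - 1) = di % st.i % (1.0 - st.i);
    dz.subvec(n, 2 * n - 1) = df % st.f % (1.0 - st.f);
    dz.subvec(2 * n, 3 * n - 1) = dgc % (1.0 - square(st.gc));
    dz.subvec(3 * n, 4 * n - 1) = do_ % st.o % (1.0 - st.o);
    g["Wx"] += dz * st.in.t();
    g["Wh"] += dz * h_prev.t();
    g["bg"] += dz;
    vec din = p.at("Wx").t() * dz;
    vec dr_prev = din.subvec(din.n_elem - W, din.n_elem - 1);
    vec dh_prev = p.at("Wh").t() * dz;
    // roll gradients to step t-1
    dh = dh_prev;
    dc = dc_prev;
    dr = dr_prev;
    du = du_prev;
    dpv = dp_prev;
    dwr = dwr_prev;
    dww = dww_prev;
    dM = dM_prev;
    dLm = dL_prev;
  }
}

// ===========================================================================
// Generic driver: loss and gradients over a minibatch.

struct Hyper {
  double lambda, eta;
  int S, N, W;
  bool relu;
  double clip;   // global gradient-norm clip (<= 0 disables)
  bool ce;       // cross-entropy over corpus logits instead of MSE
};

static Hyper read_hyper(const Rcpp::List& cfg) {
  Hyper h;
  h.lambda = cfg.containsElementNamed("lambda") ? Rcpp::as<double>(cfg["lambda"]) : 0.95;
  h.eta = cfg.containsElementNamed("eta") ? Rcpp::as<double>(cfg["eta"]) : 0.5;
  h.S = cfg.containsElementNamed("S") ? Rcpp::as<int>(cfg["S"]) : 1;
  h.N = cfg.containsElementNamed("mem_slots") ? Rcpp::as<int>(cfg["mem_slots"]) : 128;
  h.W = cfg.containsElementNamed("mem_width") ? Rcpp::as<int>(cfg["mem_width"]) : 20;
  h.relu = cfg.containsElementNamed("fw_nonlin") ?
    (Rcpp::as<std::string>(cfg["fw_nonlin"]) == "relu") : false;
  h.clip = cfg.containsElementNamed("clip") ? Rcpp::as<double>(cfg["clip"]) : 0.0;
  h.ce = cfg.containsElementNamed("loss") ?
    (Rcpp::as<std::string>(cfg["loss"]) == "ce") : false;
  return h;
}

// Loss head. MSE: 0.5||pred - e_target||^2 against the target embedding.
// CE: softmax cross-entropy over inner-product logits pred . e_w for every
// word w of the lexicon (for unit-norm embeddings the argmax of these
// logits is the cosine-retrieval answer). Returns the mean loss and fills
// dPred with d(mean loss)/d pred.
static double loss_head(const mat& pred, const ivec& targets, const mat& E,
                        bool ce, mat& dPred) {
  int B = pred.n_rows;
  double loss = 0.0;
  if (!ce) {
    mat Y(B, E.n_cols);
    for (int b = 0; b < B; ++b) Y.row(b) = E.row(targets(b));
    dPred = (pred - Y) / B;
    loss = 0.5 * accu(square(pred - Y)) / B;
  } else {
    mat logits = pred * E.t();          // B x V
    dPred = zeros<mat>(B, pred.n_cols);
    for (int b = 0; b < B; ++b) {
      rowvec l = logits.row(b);
      double mx = l.max();
      rowvec p = exp(l - mx);
      p /= accu(p);
      loss += -std::log(std::max(p(targets(b)), 1e-300)) / B;
      p(targets(b)) -= 1.0;
      dPred.row(b) = (p * E) / B;
    }
  }
  return loss;
}

// loss: (1/B) sum_b 0.5 ||pred_b - y_b||^2; accumulates grads
// E_embed provides input embeddings for X; E_loss is the candidate matrix
// the loss head scores against, with `targets` indexing its rows.
static double batch_loss_grad(const std::string& arch, const Params& p,
                              const imat& X, const ivec& targets,
                              const mat& E_embed, const mat& E_loss,
                              const Hyper& hy, Params& g) {
  int B = X.n_rows;
  double loss = 0.0;
  mat dPred;
  if (arch == "rnn") {
    RnnCache c;
    mat pred = rnn_forward(p, X, E_embed, c);
    loss = loss_head(pred, targets, E_loss, hy.ce, dPred);
    rnn_backward(p, c, dPred, g);
  } else if (arch == "lstm") {
    LstmCache c;
    mat pred = lstm_forward(p, X, E_embed, c);
    loss = loss_head(pred, targets, E_loss, hy.ce, dPred);
    lstm_backward(p, c, dPred, g);
  } else if (arch == "fastweights") {
    FwCache c;
    mat pred = fw_forward(p, X, E_embed, hy.lambda, hy.eta, hy.S, hy.relu, c);
    loss = loss_head(pred, targets, E_loss, hy.ce, dPred);
    fw_backward(p, c, dPred, hy.lambda, hy.eta, hy.S, hy.relu, g);
  } else if (arch == "dnc") {
    DncDims dm;
    dm.n = p.at("Wh").n_cols; dm.d = E_embed.n_cols; dm.N = hy.N; dm.W = hy.W;
    for (int b = 0; b < B; ++b) {
      DncCache c;
      ivec tk = X.row(b).t();
      vec pred = dnc_forward_seq(p, tk, E_embed, dm, c);
      mat pr = pred.t();
      ivec tg(1); tg(0) = targets(b);
      mat dP;
      loss += loss_head(pr, tg, E_loss, hy.ce, dP) / B;
      dnc_backward_seq(p, tk, c, dP.row(0).t() / B, dm, g);
    }
  } else {
    Rcpp::stop("unknown architecture: " + arch);
  }
  return loss;
}

// [[Rcpp::export]]
Rcpp::List sb_loss_grad_cpp(std::string arch, Rcpp::List params,
                            arma::imat X, arma::ivec targets, arma::mat E,
                            Rcpp::List cfg) {
  Params p = as_params(params);
  Params g = zeros_like(p);
  Hyper hy = read_hyper(cfg);
  double loss = batch_loss_grad(arch, p, X, targets, E, E, hy, g);
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grads") = as_list(g));
}

// [[Rcpp::export]]
arma::mat sb_predict_cpp(std::string arch, Rcpp::List params, arma::imat X,
                         arma::mat E, Rcpp::List cfg) {
  Params p = as_params(params);
  Hyper hy = read_hyper(cfg);
  if (arch == "rnn") {
    RnnCache c;
    return rnn_forward(p, X, E, c);
  } else if (arch == "lstm") {
    LstmCache c;
    return lstm_forward(p, X, E, c);
  } else if (arch == "fastweights") {
    FwCache c;
    return fw_forward(p, X, E, hy.lambda, hy.eta, hy.S, hy.relu, c);
  } else if (arch == "dnc") {
    DncDims dm;
    dm.n = p.at("Wh").n_cols; dm.d = E.n_cols; dm.N = hy.N; dm.W = hy.W;
    mat out(X.n_rows, E.n_cols);
    for (uword b = 0; b < X.n_rows; ++b) {
      DncCache c;
      ivec tk = X.row(b).t();
      out.row(b) = dnc_forward_seq(p, tk, E, dm, c).t();
    }
    return out;
  }
  Rcpp::stop("unknown architecture: " + arch);
}

// Forward pass for one sequence with full activation trace.
// [[Rcpp::export]]
Rcpp::List sb_trace_cpp(std::string arch, Rcpp::List params, arma::ivec tokens,
                        arma::mat E, Rcpp::List cfg) {
  Params p = as_params(params);
  Hyper hy = read_hyper(cfg);
  int L = tokens.n_elem;
  imat X(1, L);
  for (int t = 0; t < L; ++t) X(0, t) = tokens(t);
  if (arch == "rnn" || arch == "lstm") {
    mat pred;
    if (arch == "rnn") {
      RnnCache c;
      pred = rnn_forward(p, X, E, c);
      mat Hm(L, c.H[1].n_cols);
      for (int t = 0; t < L; ++t) Hm.row(t) = c.H[t + 1];
      return Rcpp::List::create(Rcpp::Named("prediction") = pred.row(0).t(),
                                Rcpp::Named("hidden") = Hm);
    } else {
      LstmCache c;
      pred = lstm_forward(p, X, E, c);
      mat Hm(L, c.H[1].n_cols);
      for (int t = 0; t < L; ++t) Hm.row(t) = c.H[t + 1];
      return Rcpp::List::create(Rcpp::Named("prediction") = pred.row(0).t(),
                                Rcpp::Named("hidden") = Hm);
    }
  } else if (arch == "fastweights") {
    FwCache c;
    mat pred = fw_forward(p, X, E, hy.lambda, hy.eta, hy.S, hy.relu, c);
    int n = c.H[1].n_cols;
    mat Hm(L, n), Am(L, n * n);
    mat A = zeros<mat>(n, n);
    for (int t = 0; t < L; ++t) {
      Hm.row(t) = c.H[t + 1];
      A = hy.lambda * A + hy.eta * (c.H[t].row(0).t() * c.H[t].row(0));
      Am.row(t) = vectorise(A).t();
    }
    return Rcpp::List::create(Rcpp::Named("prediction") = pred.row(0).t(),
                              Rcpp::Named("hidden") = Hm,
                              Rcpp::Named("memory") = Am);
  } else if (arch == "dnc") {
    DncDims dm;
    dm.n = p.at("Wh").n_cols; dm.d = E.n_cols; dm.N = hy.N; dm.W = hy.W;
    DncCache c;
    vec pred = dnc_forward_seq(p, tokens, E, dm, c);
    mat Hm(L, dm.n), Mm(L, dm.N * dm.W), WR(L, dm.N), WW(L, dm.N), Rv(L, dm.W);
    for (int t = 0; t < L; ++t) {
      Hm.row(t) = c.steps[t].h.t();
      Mm.row(t) = vectorise(c.steps[t].M, 1);  // row-major: slot-by-slot
      WR.row(t) = c.steps[t].wr.t();
      WW.row(t) = c.steps[t].ww.t();
      Rv.row(t) = c.steps[t].r.t();
    }
    return Rcpp::List::create(Rcpp::Named("prediction") = pred,
                              Rcpp::Named("hidden") = Hm,
                              Rcpp::Named("memory") = Mm,
                              Rcpp::Named("read_weights") = WR,
                              Rcpp::Named("write_weights") = WW,
                              Rcpp::Named("read_vector") = Rv);
  }
  Rcpp::stop("unknown architecture: " + arch);
}

// ===========================================================================
// Adam training loop. Minibatch order is drawn from R's RNG so runs are
// reproducible with set.seed().

// Candidate-restricted cross-entropy: when `cands` is non-empty it holds,
// per story, the lexicon rows (0-based) of that story's fresh fillers; the
// training corpus of a minibatch is then the first `n_base` lexicon rows
// plus the batch stories' filler rows (the batch-corpus convention of the
// unlimited regime). An empty `cands` scores against the whole lexicon.

// [[Rcpp::export]]
Rcpp::List sb_train_cpp(std::string arch, Rcpp::List params, Rcpp::List opt,
                        arma::imat X, arma::ivec targets, arma::mat E,
                        Rcpp::List cfg, double lr, int batch_size, int epochs,
                        arma::imat cands, int n_base) {
  Params p = as_params(params);
  Params m = as_params(Rcpp::as<Rcpp::List>(opt["m"]));
  Params v = as_params(Rcpp::as<Rcpp::List>(opt["v"]));
  int step = Rcpp::as<int>(opt["step"]);
  Hyper hy = read_hyper(cfg);
  int nstories = X.n_rows;
  const double b1 = 0.9, b2 = 0.999, adam_eps = 1e-8;
  Rcpp::NumericVector losses(epochs);
  Rcpp::RNGScope scope;
  for (int ep = 0; ep < epochs; ++ep) {
    // Fisher-Yates permutation from R's RNG
    std::vector<int> ord(nstories);
    for (int i = 0; i < nstories; ++i) ord[i] = i;
    for (int i = nstories - 1; i > 0; --i) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(ord[i], ord[j]);
    }
    double ep_loss = 0.0;
    int nb = 0;
    for (int s = 0; s < nstories; s += batch_size) {
      int e = std::min(s + batch_size, nstories);
      imat Xb(e - s, X.n_cols);
      ivec yb(e - s);
      for (int i = s; i < e; ++i) {
        Xb.row(i - s) = X.row(ord[i]);
        yb(i - s) = targets(ord[i]);
      }
      Params g = zeros_like(p);
      double loss;
      if (cands.n_rows == 0) {
        loss = batch_loss_grad(arch, p, Xb, yb, E, E, hy, g);
      } else {
        // batch corpus: base rows then each batch story's filler rows
        int kc = cands.n_cols;
        uvec idx(n_base + (e - s) * kc);
        for (int i = 0; i < n_base; ++i) idx(i) = i;
        for (int i = s; i < e; ++i) {
          for (int c2 = 0; c2 < kc; ++c2) {
            idx(n_base + (i - s) * kc + c2) = (uword)cands(ord[i], c2);
          }
        }
        mat Eloss = E.rows(idx);
        ivec yb2(e - s);
        for (int i = 0; i < e - s; ++i) {
          yb2(i) = -1;
          for (uword j = 0; j < idx.n_elem; ++j) {
            if ((sword)idx(j) == yb(i)) { yb2(i) = j; break; }
          }
          if (yb2(i) < 0) Rcpp::stop("target not among loss candidates");
        }
        loss = batch_loss_grad(arch, p, Xb, yb2, E, Eloss, hy, g);
      }
      if (!std::isfinite(loss)) Rcpp::stop("training diverged: non-finite loss");
      if (hy.clip > 0) {
        double sq = 0.0;
        for (Params::iterator it = g.begin(); it != g.end(); ++it) {
          sq += accu(square(it->second));
        }
        double gn = std::sqrt(sq);
        if (gn > hy.clip) {
          for (Params::iterator it = g.begin(); it != g.end(); ++it) {
            it->second *= hy.clip / gn;
          }
        }
      }
      ep_loss += loss;
      ++nb;
      ++step;
      double c1 = 1.0 - std::pow(b1, step);
      double c2 = 1.0 - std::pow(b2, step);
      for (Params::iterator it = p.begin(); it != p.end(); ++it) {
        const std::string& k = it->first;
        m[k] = b1 * m[k] + (1.0 - b1) * g[k];
        v[k] = b2 * v[k] + (1.0 - b2) * square(g[k]);
        it->second -= lr * (m[k] / c1) / (sqrt(v[k] / c2) + adam_eps);
      }
    }
    losses[ep] = ep_loss / std::max(nb, 1);
  }
  return Rcpp::List::create(
      Rcpp::Named("params") = as_list(p),
      Rcpp::Named("opt") = Rcpp::List::create(Rcpp::Named("m") = as_list(m),
                                              Rcpp::Named("v") = as_list(v),
                                              Rcpp::Named("step") = step),
      Rcpp::Named("losses") = losses);
}
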
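// Batched recurrent-cell loops (GRU and LSTM), forward and
// backprop-through-time, with post-padding masks. Only the time loop lives
// here: input-side projections (embedding lookup, X * W) and all dense
// layers are plain matrix products handled in R, so this file receives the
// precomputed per-step input projections `ain` (bias NOT included; the gate
// bias vector is added here) laid out time-major: rows [t*B, (t+1)*B) hold
// step t for a batch of B sequences.
//
// Gate column layout (H = hidden units):
//   GRU : [ z | r | c ]      (ain is (B*T) x 3H)
//   LSTM: [ i | f | o | g ]  (ain is (B*T) x 4H)
//
// A sequence with length L < T is frozen from step L on: its hidden (and
// cell) state passes through unchanged, and no gradient flows through the
// padded steps. When every sequence in the batch spans all T steps the
// masking work is skipped entirely.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline void sigm_inplace(mat& x) {
  x.transform([](double v) { return 1.0 / (1.0 + std::exp(-v)); });
}
static inline void tanh_inplace(mat& x) {
  x.transform([](double v) { return std::tanh(v); });
}

// Per-step activity mask: 1 while t < length, else 0.
static inline vec step_mask(const ivec& lengths, int t) {
  vec m(lengths.n_elem);
  for (uword b = 0; b < lengths.n_elem; ++b) m(b) = (t < lengths(b)) ? 1.0 : 0.0;
  return m;
}

// [[Rcpp::export]]
Rcpp::List gru_forward_cpp(const arma::mat& ain, const arma::rowvec& bias,
                           const arma::mat& u_zr, const arma::mat& u_c,
                           const arma::ivec& lengths, int n_steps,
                           bool keep_cache) {
  const int H = u_c.n_cols;
  const int B = lengths.n_elem;
  const bool all_active = (int)lengths.min() >= n_steps;
  mat h(B, H, fill::zeros);
  mat Z, R, C, HP;
  if (keep_cache) {
    Z.set_size(B * n_steps, H); R.set_size(B * n_steps, H);
    C.set_size(B * n_steps, H); HP.set_size(B * n_steps, H);
  }
  mat azr(B, 2 * H), ac(B, H), rh(B, H);
  for (int t = 0; t < n_steps; ++t) {
    const uword r0 = (uword)t * B, r1 = r0 + B - 1;
    azr = h * u_zr;
    azr += ain.submat(r0, 0, r1, 2 * H - 1);
    azr.each_row() += bias.cols(0, 2 * H - 1);
    sigm_inplace(azr);
    const auto z = azr.cols(0, H - 1);
    const auto r = azr.cols(H, 2 * H - 1);
    rh = r % h;
    ac = rh * u_c;
    ac += ain.submat(r0, 2 * H, r1, 3 * H - 1);
    ac.each_row() += bias.cols(2 * H, 3 * H - 1);
    tanh_inplace(ac);
    if (keep_cache) {
      Z.rows(r0, r1) = z; R.rows(r0, r1) = r;
      C.rows(r0, r1) = ac; HP.rows(r0, r1) = h;
    }
    if (all_active) {
      h = z % h + (1.0 - z) % ac;
    } else {
      mat hnew = z % h + (1.0 - z) % ac;
      vec m = step_mask(lengths, t);
      hnew.each_col() %= m;
      h.each_col() %= (1.0 - m);
      h += hnew;
    }
  }
  if (keep_cache) {
    return Rcpp::List::create(Rcpp::Named("h") = h, Rcpp::Named("z") = Z,
                              Rcpp::Named("r") = R, Rcpp::Named("c") = C,
                              Rcpp::Named("h_prev") = HP);
  }
  return Rcpp::List::create(Rcpp::Named("h") = h);
}

// [[Rcpp::export]]
Rcpp::List gru_backward_cpp(const arma::mat& dh_final, const Rcpp::List& cache,
                            const arma::mat& u_zr, const arma::mat& u_c,
                            const arma::ivec& lengths, int n_steps) {
  const int H = u_c.n_cols;
  const int B = lengths.n_elem;
  const bool all_active = (int)lengths.min() >= n_steps;
  const mat Z = cache["z"], R = cache["r"], C = cache["c"], HP = cache["h_prev"];
  mat dain(B * n_steps, 3 * H);
  mat du_zr(size(u_zr), fill::zeros), du_c(size(u_c), fill::zeros);
  mat dh = dh_final;
  mat dhn(B, H), dazr(B, 2 * H), dc(B, H), drh(B, H);
  for (int t = n_steps - 1; t >= 0; --t) {
    const uword r0 = (uword)t * B, r1 = r0 + B - 1;
    const auto z = Z.rows(r0, r1), r = R.rows(r0, r1);
    const auto c = C.rows(r0, r1), hp = HP.rows(r0, r1);
    if (all_active) {
      dhn = dh;
      dh.zeros();
    } else {
      vec m = step_mask(lengths, t);
      dhn = dh; dhn.each_col() %= m;           // gradient entering the cell
      dh.each_col() %= (1.0 - m);              // frozen rows pass through
    }
    dazr.cols(0, H - 1) = dhn % (hp - c) % z % (1.0 - z);      // dz
    dc = dhn % (1.0 - z) % (1.0 - c % c);
    drh = dc * u_c.t();
    dazr.cols(H, 2 * H - 1) = drh % hp % r % (1.0 - r);        // dr
    du_zr += hp.t() * dazr;
    du_c += (r % hp).t() * dc;
    dain.submat(r0, 0, r1, 2 * H - 1) = dazr;
    dain.submat(r0, 2 * H, r1, 3 * H - 1) = dc;
    dh += dhn % z + dazr * u_zr.t() + drh % r;
  }
  return Rcpp::List::create(Rcpp::Named("dain") = dain,
                            Rcpp::Named("du_zr") = du_zr,
                            Rcpp::Named("du_c") = du_c);
}

// [[Rcpp::export]]
Rcpp::List lstm_forward_cpp(const arma::mat& ain, const arma::rowvec& bias,
                            const arma::mat& u, const arma::ivec& lengths,
                            int n_steps, bool keep_cache) {
  const int H = u.n_rows;
  const int B = lengths.n_elem;
  const bool all_active = (int)lengths.min() >= n_steps;
  mat h(B, H, fill::zeros), cst(B, H, fill::zeros);
  mat I, F, O, G, CP, TC, HP;
  if (keep_cache) {
    I.set_size(B * n_steps, H); F.set_size(B * n_steps, H);
    O.set_size(B * n_steps, H); G.set_size(B * n_steps, H);
    CP.set_size(B * n_steps, H); TC.set_size(B * n_steps, H);
    HP.set_size(B * n_steps, H);
  }
  mat a(B, 4 * H), tc(B, H);
  for (int t = 0; t < n_steps; ++t) {
    const uword r0 = (uword)t * B, r1 = r0 + B - 1;
    a = h * u;
    a += ain.rows(r0, r1);
    a.each_row() += bias;
    mat asig = a.cols(0, 3 * H - 1);
    sigm_inplace(asig);
    mat g = a.cols(3 * H, 4 * H - 1);
    tanh_inplace(g);
    const auto i = asig.cols(0, H - 1);
    const auto f = asig.cols(H, 2 * H - 1);
    const auto o = asig.cols(2 * H, 3 * H - 1);
    mat cnew = f % cst + i % g;
    tc = tanh(cnew);
    mat hnew = o % tc;
    if (keep_cache) {
      I.rows(r0, r1) = i; F.rows(r0, r1) = f; O.rows(r0, r1) = o;
      G.rows(r0, r1) = g; CP.rows(r0, r1) = cst; TC.rows(r0, r1) = tc;
      HP.rows(r0, r1) = h;
    }
    if (all_active) {
      h = hnew; cst = cnew;
    } else {
      vec m = step_mask(lengths, t);
      hnew.each_col() %= m; cnew.each_col() %= m;
      h.each_col() %= (1.0 - m); cst.each_col() %= (1.0 - m);
      h += hnew; cst += cnew;
    }
  }
  if (keep_cache) {
    return Rcpp::List::create(Rcpp::Named("h") = h, Rcpp::Named("i") = I,
                              Rcpp::Named("f") = F, Rcpp::Named("o") = O,
                              Rcpp::Named("g") = G, Rcpp::Named("c_prev") = CP,
                              Rcpp::Named("tanh_c") = TC,
                              Rcpp::Named("h_prev") = HP);
  }
  return Rcpp::List::create(Rcpp::Named("h") = h);
}

// [[Rcpp::export]]
Rcpp::List lstm_backward_cpp(const arma::mat& dh_final, const Rcpp::List& cache,
                             const arma::mat& u, const arma::ivec& lengths,
                             int n_steps) {
  const int H = u.n_rows;
  const int B = lengths.n_elem;
  const bool all_active = (int)lengths.min() >= n_steps;
  const mat I = cache["i"], F = cache["f"], O = cache["o"], G = cache["g"];
  const mat CP = cache["c_prev"], TC = cache["tanh_c"], HP = cache["h_prev"];
  mat dain(B * n_steps, 4 * H);
  mat du(size(u), fill::zeros);
  mat dh = dh_final, dc(B, H, fill::zeros);
  mat dhn(B, H), dcnew(B, H), da(B, 4 * H);
  for (int t = n_steps - 1; t >= 0; --t) {
    const uword r0 = (uword)t * B, r1 = r0 + B - 1;
    const auto i = I.rows(r0, r1), f = F.rows(r0, r1), o = O.rows(r0, r1);
    const auto g = G.rows(r0, r1), cp = CP.rows(r0, r1), tc = TC.rows(r0, r1);
    if (all_active) {
      dhn = dh; dh.zeros();
      dcnew = dc + dhn % o % (1.0 - tc % tc);
      dc.zeros();
    } else {
      vec m = step_mask(lengths, t);
      dhn = dh; dhn.each_col() %= m;
      dh.each_col() %= (1.0 - m);
      dcnew = dc; dcnew.each_col() %= m;
      dcnew += dhn % o % (1.0 - tc % tc);
      dc.each_col() %= (1.0 - m);
    }
    da.cols(0, H - 1) = dcnew % g % i % (1.0 - i);             // di
    da.cols(H, 2 * H - 1) = dcnew % cp % f % (1.0 - f);        // df
    da.cols(2 * H, 3 * H - 1) = dhn % tc % o % (1.0 - o);      // do
    da.cols(3 * H, 4 * H - 1) = dcnew % i % (1.0 - g % g);     // dg
    du += HP.rows(r0, r1).t() * da;
    dain.rows(r0, r1) = da;
    dh += da * u.t();
    dc += dcnew % f;
  }
  return Rcpp::List::create(Rcpp::Named("dain") = dain,
                            Rcpp::Named("du") = du);
}
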
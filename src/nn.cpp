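// Forward and backward passes of the hybrid convolutional / bidirectional
// GRU sequence classifier. Shapes:
//   X      : (L, 4, N) one-hot cube, one slice per sequence
//   M      : (m, 4, F) filter bank (as an R array); flattened column-major a
//            filter is a contiguous (m*4)-vector, so the bank acts as a
//            (m*4) x F matrix on im2col patches
//   GRU    : per direction Wz,Wr,Wh (F x H), Uz,Ur,Uh (H x H), bz,br,bh (H)
//   dense  : (2H x D) + bias, then scalar projection + bias, sigmoid output
// All randomness (init, shuffling, dropout masks) lives on the R side; this
// code is deterministic.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

struct GruWeights {
  mat Wz, Wr, Wh, Uz, Ur, Uh;
  rowvec bz, br, bh;
};

static GruWeights gru_from_list(const Rcpp::List& g) {
  GruWeights w;
  w.Wz = Rcpp::as<mat>(g["Wz"]); w.Wr = Rcpp::as<mat>(g["Wr"]);
  w.Wh = Rcpp::as<mat>(g["Wh"]); w.Uz = Rcpp::as<mat>(g["Uz"]);
  w.Ur = Rcpp::as<mat>(g["Ur"]); w.Uh = Rcpp::as<mat>(g["Uh"]);
  w.bz = Rcpp::as<rowvec>(g["bz"]); w.br = Rcpp::as<rowvec>(g["br"]);
  w.bh = Rcpp::as<rowvec>(g["bh"]);
  return w;
}

struct GruCache {
  cube Z, R, Hc, H;  // (N, H, T) in processed (time) order
};

// Runs one GRU direction over the pooled feature cube (N, F, T).
// If reverse, time steps are consumed T-1 .. 0 but caches are stored in
// processed order. Update rule: h_t = (1 - z_t) % h_{t-1} + z_t % hcand_t.
static mat gru_forward(const cube& pooled, const GruWeights& w, bool reverse,
                       GruCache& cache) {
  const uword N = pooled.n_rows, T = pooled.n_slices, H = w.Uz.n_rows;
  cache.Z.set_size(N, H, T); cache.R.set_size(N, H, T);
  cache.Hc.set_size(N, H, T); cache.H.set_size(N, H, T);
  mat h(N, H, fill::zeros);
  for (uword s = 0; s < T; ++s) {
    uword t = reverse ? T - 1 - s : s;
    const mat& xt = pooled.slice(t);
    mat z = xt * w.Wz + h * w.Uz; z.each_row() += w.bz;
    z = 1.0 / (1.0 + exp(-z));
    mat r = xt * w.Wr + h * w.Ur; r.each_row() += w.br;
    r = 1.0 / (1.0 + exp(-r));
    mat hc = xt * w.Wh + (r % h) * w.Uh; hc.each_row() += w.bh;
    hc = tanh(hc);
    mat hnew = (1.0 - z) % h + z % hc;
    cache.Z.slice(s) = z; cache.R.slice(s) = r;
    cache.Hc.slice(s) = hc; cache.H.slice(s) = hnew;
    h = hnew;
  }
  return h;
}

struct GruGrads {
  mat dWz, dWr, dWh, dUz, dUr, dUh;
  rowvec dbz, dbr, dbh;
};

// BPTT through one direction. dh_last is the loss gradient at the final
// hidden state; accumulates input gradients into dpooled (N, F, T).
static GruGrads gru_backward(const cube& pooled, const GruWeights& w,
                             bool reverse, const GruCache& cache,
                             const mat& dh_last, cube& dpooled) {
  const uword N = pooled.n_rows, T = pooled.n_slices;
  const uword F = w.Wz.n_rows, H = w.Uz.n_rows;
  GruGrads g;
  g.dWz.zeros(F, H); g.dWr.zeros(F, H); g.dWh.zeros(F, H);
  g.dUz.zeros(H, H); g.dUr.zeros(H, H); g.dUh.zeros(H, H);
  g.dbz.zeros(H); g.dbr.zeros(H); g.dbh.zeros(H);
  mat dh = dh_last;
  for (uword s = T; s-- > 0;) {
    uword t = reverse ? T - 1 - s : s;
    const mat& xt = pooled.slice(t);
    const mat& z = cache.Z.slice(s);
    const mat& r = cache.R.slice(s);
    const mat& hc = cache.Hc.slice(s);
    mat hprev = (s == 0) ? mat(N, H, fill::zeros) : mat(cache.H.slice(s - 1));

    mat dhc = dh % z;
    mat dz = dh % (hc - hprev);
    mat dah = dhc % (1.0 - hc % hc);
    mat daz = dz % z % (1.0 - z);
    mat dhprev = dh % (1.0 - z);

    g.dWh += xt.t() * dah;
    g.dUh += (r % hprev).t() * dah;
    g.dbh += sum(dah, 0);
    mat drh = dah * w.Uh.t();          // grad wrt (r % hprev)
    mat dr = drh % hprev;
    dhprev += drh % r;
    mat dar = dr % r % (1.0 - r);

    g.dWz += xt.t() * daz; g.dUz += hprev.t() * daz; g.dbz += sum(daz, 0);
    g.dWr += xt.t() * dar; g.dUr += hprev.t() * dar; g.dbr += sum(dar, 0);
    dhprev += daz * w.Uz.t() + dar * w.Ur.t();

    dpooled.slice(t) += daz * w.Wz.t() + dar * w.Wr.t() + dah * w.Wh.t();
    dh = dhprev;
  }
  return g;
}

static Rcpp::List gru_grads_to_list(const GruGrads& g) {
  return Rcpp::List::create(
      Rcpp::Named("Wz") = g.dWz, Rcpp::Named("Wr") = g.dWr,
      Rcpp::Named("Wh") = g.dWh, Rcpp::Named("Uz") = g.dUz,
      Rcpp::Named("Ur") = g.dUr, Rcpp::Named("Uh") = g.dUh,
      Rcpp::Named("bz") = g.dbz.t(), Rcpp::Named("br") = g.dbr.t(),
      Rcpp::Named("bh") = g.dbh.t());
}

// Main entry: forward pass, optionally with the mean cross-entropy loss and
// analytic gradients for every parameter group. `mask` is the (already
// scaled) inverted-dropout mask of shape (N, F, T) or NULL.
// [[Rcpp::export(name = ".cpp_nn_run")]]
Rcpp::List cpp_nn_run(const Rcpp::List& params, int pool_size,
                      const arma::cube& X,
                      Rcpp::Nullable<Rcpp::NumericVector> mask_,
                      Rcpp::Nullable<Rcpp::NumericVector> y_,
                      bool want_grad) {
  const cube M = Rcpp::as<cube>(params["M"]);        // (m, 4, F)
  const vec conv_b = Rcpp::as<vec>(params["conv_b"]);
  const GruWeights gf = gru_from_list(params["gru_fwd"]);
  const GruWeights gb = gru_from_list(params["gru_bwd"]);
  const mat dense_W = Rcpp::as<mat>(params["dense_W"]); // (2H, D)
  const rowvec dense_b = Rcpp::as<rowvec>(params["dense_b"]);
  const vec out_w = Rcpp::as<vec>(params["out_w"]);     // (D)
  const double out_b = Rcpp::as<double>(params["out_b"]);

  const uword L = X.n_rows, N = X.n_slices;
  const uword m = M.n_rows, F = M.n_slices;
  const uword Tc = L - m + 1;                 // valid conv positions
  const uword p = (uword)pool_size;
  const uword T = Tc / p;                     // truncating pool
  const uword H = gf.Uz.n_rows;
  if (T < 1) Rcpp::stop("pooled length is zero: pool size too large");

  // filter bank as (m*4) x F matrix (shares memory layout with the cube)
  const mat Wc((double*)M.memptr(), m * 4, F);

  cube P(Tc, m * 4, N);        // im2col patches per sequence
  cube Apre(Tc, F, N);         // pre-ReLU conv activations
  cube pooled(N, F, T);        // max-pooled (pre-ReLU max, then ReLU)
  ucube amax(T, F, N);         // argmax row in Apre per pooled cell
  for (uword s = 0; s < N; ++s) {
    const mat& xs = X.slice(s);
    mat& Ps = P.slice(s);
    // column j + m*c of the patch matrix is channel c shifted by j
    for (uword c = 0; c < 4; ++c) {
      for (uword j = 0; j < m; ++j) {
        Ps.col(j + m * c) = xs(span(j, j + Tc - 1), c);
      }
    }
    mat A = Ps * Wc;
    A.each_row() += conv_b.t();
    Apre.slice(s) = A;
    for (uword t = 0; t < T; ++t) {
      for (uword f = 0; f < F; ++f) {
        uword best = t * p;
        double bv = A(best, f);
        for (uword j = 1; j < p; ++j) {
          if (A(t * p + j, f) > bv) { bv = A(t * p + j, f); best = t * p + j; }
        }
        amax(t, f, s) = best;
        pooled(s, f, t) = bv > 0.0 ? bv : 0.0;   // ReLU commutes with max
      }
    }
  }

  bool use_mask = mask_.isNotNull();
  cube mask;
  if (use_mask) {
    Rcpp::NumericVector mv(mask_);
    mask = cube(mv.begin(), N, F, T);           // copies
    pooled %= mask;
  }

  GruCache cf, cb;
  mat hf = gru_forward(pooled, gf, false, cf);
  mat hb = gru_forward(pooled, gb, true, cb);
  mat concat = join_rows(hf, hb);               // (N, 2H)
  mat Dpre = concat * dense_W;
  Dpre.each_row() += dense_b;
  mat D = Dpre;                                 // ReLU
  D.elem(find(D < 0.0)).zeros();
  vec logits = D * out_w + out_b;
  vec scores = 1.0 / (1.0 + exp(-logits));
  if (!scores.is_finite()) {
    Rcpp::stop("non-finite activation in forward pass (divergence)");
  }

  Rcpp::List out;
  out["scores"] = scores;

  if (y_.isNull()) return out;
  vec y = Rcpp::as<vec>(Rcpp::NumericVector(y_));
  vec sc = clamp(scores, 1e-12, 1.0 - 1e-12);
  double loss = -mean(y % log(sc) + (1.0 - y) % log(1.0 - sc));
  out["loss"] = loss;
  if (!want_grad) return out;

  // ---- backward ----
  vec dlogit = (scores - y) / (double)N;
  vec dout_w = D.t() * dlogit;
  double dout_b = accu(dlogit);
  mat dD = dlogit * out_w.t();                  // (N, D)
  dD %= conv_to<mat>::from(Dpre > 0.0);
  mat ddense_W = concat.t() * dD;
  rowvec ddense_b = sum(dD, 0);
  mat dconcat = dD * dense_W.t();

  cube dpooled(N, F, T, fill::zeros);
  GruGrads dgf = gru_backward(pooled, gf, false, cf,
                              dconcat.cols(0, H - 1), dpooled);
  GruGrads dgb = gru_backward(pooled, gb, true, cb,
                              dconcat.cols(H, 2 * H - 1), dpooled);
  if (use_mask) dpooled %= mask;

  mat dWc(m * 4, F, fill::zeros);
  vec dconv_b(F, fill::zeros);
  for (uword s = 0; s < N; ++s) {
    mat dA(Tc, F, fill::zeros);
    for (uword t = 0; t < T; ++t) {
      for (uword f = 0; f < F; ++f) {
        // gradient flows only through the max element, and only if the
        // pre-ReLU max was positive
        if (Apre(amax(t, f, s), f, s) > 0.0) {
          dA(amax(t, f, s), f) += dpooled(s, f, t);
        }
      }
    }
    dWc += P.slice(s).t() * dA;
    dconv_b += sum(dA, 0).t();
  }
  cube dM(dWc.memptr(), m, 4, F);               // reshape back to bank layout

  out["grads"] = Rcpp::List::create(
      Rcpp::Named("M") = dM, Rcpp::Named("conv_b") = dconv_b,
      Rcpp::Named("gru_fwd") = gru_grads_to_list(dgf),
      Rcpp::Named("gru_bwd") = gru_grads_to_list(dgb),
      Rcpp::Named("dense_W") = ddense_W,
      Rcpp::Named("dense_b") = ddense_b.t(),
      Rcpp::Named("out_w") = dout_w, Rcpp::Named("out_b") = dout_b);
  return out;
}
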
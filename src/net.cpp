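// Forward/backward passes of the residue-pair-encoding affinity network.
//
// Data layout conventions:
//  * codes: n x 680 integer matrix from encode_dataset(); flat position
//    i + 34*j (0-based) holds the pair code of matrix cell (i, j).
//  * Activations are (channels x n*L) matrices, "sample-major": column
//    s*L + t is position t of sample s. The LSTM stage uses a
//    "position-major" layout (column t*n + s) so each time step is a
//    contiguous block.
//  * Conv weights: (C_out x C_in*k), tap u / input channel c at column
//    u*C_in + c. Biases are column vectors.
//
// The sequence axis is never downsampled before the final convolution:
// convs use "same" padding and both max pools slide with stride 1 over
// clipped windows, so the axis stays L = 20 until the final valid
// kernel-9 convolution leaves 12 positions (one per core window frame).

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat pget(const Rcpp::List& p, const std::string& nm) {
  return Rcpp::as<mat>(p[nm]);
}

// ---- im2col / col2im for same-padded 1-D convolution ---------------------

static mat im2col_same(const mat& X, int n, int L, int k) {
  const int C = X.n_rows;
  const int pad = (k - 1) / 2;
  mat col(C * k, n * L, fill::zeros);
  for (int s = 0; s < n; ++s) {
    for (int t = 0; t < L; ++t) {
      const int cidx = s * L + t;
      for (int u = 0; u < k; ++u) {
        const int tp = t + u - pad;
        if (tp >= 0 && tp < L)
          col.submat(u * C, cidx, (u + 1) * C - 1, cidx) = X.col(s * L + tp);
      }
    }
  }
  return col;
}

static void col2im_same_add(mat& dX, const mat& dcol, int n, int L, int k) {
  const int C = dX.n_rows;
  const int pad = (k - 1) / 2;
  for (int s = 0; s < n; ++s) {
    for (int t = 0; t < L; ++t) {
      const int cidx = s * L + t;
      for (int u = 0; u < k; ++u) {
        const int tp = t + u - pad;
        if (tp >= 0 && tp < L)
          dX.col(s * L + tp) += dcol.submat(u * C, cidx, (u + 1) * C - 1, cidx);
      }
    }
  }
}

// ---- stride-1 clipped-window max pooling ---------------------------------

// w = 2: window [t, t+1]; w = 3: window [t-1, t+1]; clipped at the edges.
static mat maxpool_s1(const mat& X, int n, int L, int w, umat& argmax) {
  const int C = X.n_rows;
  mat Y(C, n * L);
  argmax.set_size(C, n * L);
  const int lo_off = (w == 3) ? -1 : 0;
  const int hi_off = (w == 3) ? 1 : (w - 1);
  for (int s = 0; s < n; ++s) {
    for (int t = 0; t < L; ++t) {
      const int lo = std::max(0, t + lo_off);
      const int hi = std::min(L - 1, t + hi_off);
      const int cidx = s * L + t;
      for (int c = 0; c < C; ++c) {
        double best = X(c, s * L + lo);
        int besti = lo;
        for (int tp = lo + 1; tp <= hi; ++tp) {
          const double v = X(c, s * L + tp);
          if (v > best) { best = v; besti = tp; }
        }
        Y(c, cidx) = best;
        argmax(c, cidx) = besti;
      }
    }
  }
  return Y;
}

static void maxpool_s1_back(mat& dX, const mat& dY, const umat& argmax,
                            int n, int L) {
  const int C = dX.n_rows;
  for (int s = 0; s < n; ++s)
    for (int t = 0; t < L; ++t) {
      const int cidx = s * L + t;
      for (int c = 0; c < C; ++c)
        dX(c, s * L + argmax(c, cidx)) += dY(c, cidx);
    }
}

// ---- layout conversion ---------------------------------------------------

static mat to_posmajor(const mat& X, int n, int L) {
  mat Y(X.n_rows, X.n_cols);
  for (int s = 0; s < n; ++s)
    for (int t = 0; t < L; ++t)
      Y.col(t * n + s) = X.col(s * L + t);
  return Y;
}

static mat to_samplemajor(const mat& X, int n, int L) {
  mat Y(X.n_rows, X.n_cols);
  for (int s = 0; s < n; ++s)
    for (int t = 0; t < L; ++t)
      Y.col(s * L + t) = X.col(t * n + s);
  return Y;
}

// ---- LSTM (unidirectional, full hidden sequence returned) ----------------

struct LstmCache {
  mat G;   // activated gates (4H x n*L, position-major): i, f, g, o
  mat Cst; // cell states (H x n*L)
  mat Tc;  // tanh(cell state)
};

static mat lstm_forward(const mat& Wx, const mat& Wh, const vec& b,
                        const mat& Xp, int n, int L, LstmCache& cc) {
  const int H = Wh.n_cols;
  mat Hseq(H, n * L);
  cc.G.set_size(4 * H, n * L);
  cc.Cst.set_size(H, n * L);
  cc.Tc.set_size(H, n * L);
  mat h_prev(H, n, fill::zeros), c_prev(H, n, fill::zeros);
  for (int t = 0; t < L; ++t) {
    const span cols(t * n, (t + 1) * n - 1);
    mat G = Wx * Xp.cols(cols) + Wh * h_prev;
    G.each_col() += b;
    mat i = 1.0 / (1.0 + exp(-G.rows(0, H - 1)));
    mat f = 1.0 / (1.0 + exp(-G.rows(H, 2 * H - 1)));
    mat g = tanh(G.rows(2 * H, 3 * H - 1));
    mat o = 1.0 / (1.0 + exp(-G.rows(3 * H, 4 * H - 1)));
    mat c = f % c_prev + i % g;
    mat tc = tanh(c);
    mat h = o % tc;
    cc.G.submat(0, t * n, H - 1, (t + 1) * n - 1) = i;
    cc.G.submat(H, t * n, 2 * H - 1, (t + 1) * n - 1) = f;
    cc.G.submat(2 * H, t * n, 3 * H - 1, (t + 1) * n - 1) = g;
    cc.G.submat(3 * H, t * n, 4 * H - 1, (t + 1) * n - 1) = o;
    cc.Cst.cols(cols) = c;
    cc.Tc.cols(cols) = tc;
    Hseq.cols(cols) = h;
    h_prev = h; c_prev = c;
  }
  return Hseq;
}

static mat lstm_backward(const mat& Wx, const mat& Wh, const mat& Xp,
                         const mat& Hseq, const LstmCache& cc, const mat& dHup,
                         int n, int L, mat& dWx, mat& dWh, vec& db) {
  const int H = Wh.n_cols;
  dWx.zeros(Wx.n_rows, Wx.n_cols);
  dWh.zeros(Wh.n_rows, Wh.n_cols);
  db.zeros(4 * H);
  mat dXp(Xp.n_rows, Xp.n_cols, fill::zeros);
  mat dG_next(4 * H, n, fill::zeros);
  mat dc_next(H, n, fill::zeros);
  mat f_next(H, n, fill::zeros);
  for (int t = L - 1; t >= 0; --t) {
    const span cols(t * n, (t + 1) * n - 1);
    mat i = cc.G.submat(0, t * n, H - 1, (t + 1) * n - 1);
    mat f = cc.G.submat(H, t * n, 2 * H - 1, (t + 1) * n - 1);
    mat g = cc.G.submat(2 * H, t * n, 3 * H - 1, (t + 1) * n - 1);
    mat o = cc.G.submat(3 * H, t * n, 4 * H - 1, (t + 1) * n - 1);
    mat tc = cc.Tc.cols(cols);
    mat dh = dHup.cols(cols) + Wh.t() * dG_next;
    mat dc = dh % o % (1.0 - tc % tc) + dc_next % f_next;
    mat c_prev = (t == 0) ? mat(H, n, fill::zeros) : mat(cc.Cst.cols(span((t - 1) * n, t * n - 1)));
    mat h_prev = (t == 0) ? mat(H, n, fill::zeros) : mat(Hseq.cols(span((t - 1) * n, t * n - 1)));
    mat dG(4 * H, n);
    dG.rows(0, H - 1)         = (dc % g) % i % (1.0 - i);
    dG.rows(H, 2 * H - 1)     = (dc % c_prev) % f % (1.0 - f);
    dG.rows(2 * H, 3 * H - 1) = (dc % i) % (1.0 - g % g);
    dG.rows(3 * H, 4 * H - 1) = (dh % tc) % o % (1.0 - o);
    dWx += dG * Xp.cols(cols).t();
    dWh += dG * h_prev.t();
    db += sum(dG, 1);
    dXp.cols(cols) = Wx.t() * dG;
    dG_next = dG;
    dc_next = dc;
    f_next = f;
  }
  return dXp;
}

// ---- the full network ----------------------------------------------------

// Runs a forward pass over a batch; when `y` is non-null also runs the
// backward pass and returns MSE loss and gradients for every parameter.
// [[Rcpp::export]]
Rcpp::List rpe_net_run(Rcpp::List params, Rcpp::IntegerMatrix codes,
                       Rcpp::List cfg, Rcpp::Nullable<Rcpp::NumericVector> y_,
                       bool training, int dropout_seed) {
  const int n = codes.nrow();
  const int L = 20, LM = 34;
  const int E = Rcpp::as<int>(cfg["embedding_dim"]);
  const ivec c1_k = Rcpp::as<ivec>(cfg["conv1_k"]);
  const ivec c1_c = Rcpp::as<ivec>(cfg["conv1_c"]);
  const ivec c2_k = Rcpp::as<ivec>(cfg["conv2_k"]);
  const ivec c2_c = Rcpp::as<ivec>(cfg["conv2_c"]);
  const int C3 = Rcpp::as<int>(cfg["conv3_c"]);
  const int H = Rcpp::as<int>(cfg["lstm_hidden"]);
  const int CF = Rcpp::as<int>(cfg["final_c"]);
  const int FINK = Rcpp::as<int>(cfg["final_k"]);
  const int FC = Rcpp::as<int>(cfg["fc_dim"]);
  const double drop = Rcpp::as<double>(cfg["dropout"]);
  const bool fuse_bias = Rcpp::as<bool>(cfg["fuse_bias"]);
  const int L2 = L - FINK + 1;
  const bool compute_grad = y_.isNotNull();

  const mat emb = pget(params, "emb");           // 442 x E
  if ((int)emb.n_rows != 442 || (int)emb.n_cols != E)
    Rcpp::stop("embedding table must be 442 x embedding_dim");
  const mat fuse_W = pget(params, "fuse_W");     // 34E x E
  const mat fuse_b = pget(params, "fuse_b");     // E x 1

  // gather embeddings: X (34E x n*L), column s*L+j holds the 34 stacked
  // embedding vectors of peptide column j
  mat X(LM * E, n * L, fill::zeros);
  for (int s = 0; s < n; ++s)
    for (int j = 0; j < L; ++j) {
      const int cidx = s * L + j;
      for (int i = 0; i < LM; ++i) {
        const int code = codes(s, i + LM * j);
        if (code < 0 || code > 441) Rcpp::stop("pair code out of range 0..441");
        if (code != 0)
          X.submat(i * E, cidx, (i + 1) * E - 1, cidx) = emb.row(code).t();
      }
    }

  // fusion: (34,1) convolution contracting the MHC axis (linear)
  mat I = fuse_W.t() * X;                        // E x n*L
  if (fuse_bias) I.each_col() += fuse_b.col(0);

  // conv1: parallel same-padded convs, ReLU, channel concat
  const int n1 = c1_k.n_elem;
  std::vector<mat> col1(n1), pre1(n1);
  int C1 = 0;
  for (int b = 0; b < n1; ++b) C1 += c1_c[b];
  mat A1(C1, n * L);
  {
    int off = 0;
    for (int b = 0; b < n1; ++b) {
      col1[b] = im2col_same(I, n, L, c1_k[b]);
      mat W = pget(params, "c1_W_" + std::to_string(b + 1));
      mat bb = pget(params, "c1_b_" + std::to_string(b + 1));
      pre1[b] = W * col1[b];
      pre1[b].each_col() += bb.col(0);
      A1.rows(off, off + c1_c[b] - 1) = clamp(pre1[b], 0.0, datum::inf);
      off += c1_c[b];
    }
  }

  umat am1;
  mat P1 = maxpool_s1(A1, n, L, Rcpp::as<int>(cfg["pool1"]), am1);

  // dropout after pooling stages (inverted scaling, train only)
  std::mt19937_64 rng(static_cast<uint64_t>(dropout_seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  mat D1;
  if (training && drop > 0) {
    D1.set_size(P1.n_rows, P1.n_cols);
    for (uword idx = 0; idx < D1.n_elem; ++idx)
      D1(idx) = (unif(rng) < drop) ? 0.0 : 1.0 / (1.0 - drop);
    P1 %= D1;
  }

  // conv2
  const int n2 = c2_k.n_elem;
  std::vector<mat> col2(n2), pre2(n2);
  int C2 = 0;
  for (int b = 0; b < n2; ++b) C2 += c2_c[b];
  mat A2(C2, n * L);
  {
    int off = 0;
    for (int b = 0; b < n2; ++b) {
      col2[b] = im2col_same(P1, n, L, c2_k[b]);
      mat W = pget(params, "c2_W_" + std::to_string(b + 1));
      mat bb = pget(params, "c2_b_" + std::to_string(b + 1));
      pre2[b] = W * col2[b];
      pre2[b].each_col() += bb.col(0);
      A2.rows(off, off + c2_c[b] - 1) = clamp(pre2[b], 0.0, datum::inf);
      off += c2_c[b];
    }
  }

  umat am2;
  mat P2 = maxpool_s1(A2, n, L, Rcpp::as<int>(cfg["pool2"]), am2);
  mat D2;
  if (training && drop > 0) {
    D2.set_size(P2.n_rows, P2.n_cols);
    for (uword idx = 0; idx < D2.n_elem; ++idx)
      D2(idx) = (unif(rng) < drop) ? 0.0 : 1.0 / (1.0 - drop);
    P2 %= D2;
  }

  // conv3 (kernel 1)
  const mat c3_W = pget(params, "c3_W"), c3_b = pget(params, "c3_b");
  mat pre3 = c3_W * P2;
  pre3.each_col() += c3_b.col(0);
  mat A3 = clamp(pre3, 0.0, datum::inf);        // C3 x n*L

  // two parallel LSTM blocks (1-layer and 2-layer), full sequences
  mat Xp = to_posmajor(A3, n, L);
  LstmCache ccA, ccB1, ccB2;
  const mat lA1_Wx = pget(params, "lA1_Wx"), lA1_Wh = pget(params, "lA1_Wh");
  const mat lB1_Wx = pget(params, "lB1_Wx"), lB1_Wh = pget(params, "lB1_Wh");
  const mat lB2_Wx = pget(params, "lB2_Wx"), lB2_Wh = pget(params, "lB2_Wh");
  const vec lA1_b = pget(params, "lA1_b").col(0);
  const vec lB1_b = pget(params, "lB1_b").col(0);
  const vec lB2_b = pget(params, "lB2_b").col(0);
  mat HA = lstm_forward(lA1_Wx, lA1_Wh, lA1_b, Xp, n, L, ccA);
  mat HB1 = lstm_forward(lB1_Wx, lB1_Wh, lB1_b, Xp, n, L, ccB1);
  mat HB2 = lstm_forward(lB2_Wx, lB2_Wh, lB2_b, HB1, n, L, ccB2);

  mat Hcat(2 * H, n * L);
  Hcat.rows(0, H - 1) = to_samplemajor(HA, n, L);
  Hcat.rows(H, 2 * H - 1) = to_samplemajor(HB2, n, L);

  // final valid convolution, kernel = core width 9
  mat colF(2 * H * FINK, n * L2);
  for (int s = 0; s < n; ++s)
    for (int t = 0; t < L2; ++t)
      for (int u = 0; u < FINK; ++u)
        colF.submat(u * 2 * H, s * L2 + t, (u + 1) * 2 * H - 1, s * L2 + t) =
          Hcat.col(s * L + t + u);
  const mat fin_W = pget(params, "fin_W"), fin_b = pget(params, "fin_b");
  mat preF = fin_W * colF;
  preF.each_col() += fin_b.col(0);
  mat Fm = clamp(preF, 0.0, datum::inf);        // CF x n*L2

  // flatten (contiguous per sample), FC + sigmoid head
  mat Z0(const_cast<double*>(Fm.memptr()), CF * L2, n, false, true);
  const mat fc_W = pget(params, "fc_W"), fc_b = pget(params, "fc_b");
  mat preZ = fc_W * Z0;
  preZ.each_col() += fc_b.col(0);
  mat Z1 = clamp(preZ, 0.0, datum::inf);        // FC x n
  const mat out_w = pget(params, "out_w"), out_b = pget(params, "out_b");
  rowvec logits = out_w * Z1 + out_b(0, 0);
  rowvec yhat = 1.0 / (1.0 + exp(-logits));

  if (!yhat.is_finite()) Rcpp::stop("non-finite activations in output head");

  if (!compute_grad) {
    return Rcpp::List::create(Rcpp::Named("yhat") = Rcpp::wrap(conv_to<vec>::from(yhat)));
  }

  // ---- backward ----------------------------------------------------------
  const vec y = Rcpp::as<vec>(y_.get());
  if ((int)y.n_elem != n) Rcpp::stop("y length mismatch");
  const rowvec resid = yhat - y.t();
  const double loss = accu(square(resid)) / n;

  Rcpp::List grads;
  rowvec dlogit = (2.0 / n) * resid % yhat % (1.0 - yhat);
  grads["out_w"] = Rcpp::wrap(mat(dlogit * Z1.t()));
  grads["out_b"] = Rcpp::wrap(mat(1, 1, fill::value(accu(dlogit))));
  mat dZ1 = out_w.t() * dlogit;
  dZ1 %= conv_to<mat>::from(preZ > 0);
  grads["fc_W"] = Rcpp::wrap(mat(dZ1 * Z0.t()));
  grads["fc_b"] = Rcpp::wrap(mat(sum(dZ1, 1)));
  mat dZ0 = fc_W.t() * dZ1;                     // (CF*L2) x n
  mat dF(const_cast<double*>(dZ0.memptr()), CF, n * L2, false, true);
  mat dpreF = dF % conv_to<mat>::from(preF > 0);
  grads["fin_W"] = Rcpp::wrap(mat(dpreF * colF.t()));
  grads["fin_b"] = Rcpp::wrap(mat(sum(dpreF, 1)));
  mat dcolF = fin_W.t() * dpreF;
  mat dHcat(2 * H, n * L, fill::zeros);
  for (int s = 0; s < n; ++s)
    for (int t = 0; t < L2; ++t)
      for (int u = 0; u < FINK; ++u)
        dHcat.col(s * L + t + u) +=
          dcolF.submat(u * 2 * H, s * L2 + t, (u + 1) * 2 * H - 1, s * L2 + t);

  mat dHA = to_posmajor(dHcat.rows(0, H - 1), n, L);
  mat dHB2 = to_posmajor(dHcat.rows(H, 2 * H - 1), n, L);
  mat dWx, dWh; vec db;
  mat dXpA = lstm_backward(lA1_Wx, lA1_Wh, Xp, HA, ccA, dHA, n, L, dWx, dWh, db);
  grads["lA1_Wx"] = Rcpp::wrap(dWx); grads["lA1_Wh"] = Rcpp::wrap(dWh);
  grads["lA1_b"] = Rcpp::wrap(mat(db));
  mat dHB1 = lstm_backward(lB2_Wx, lB2_Wh, HB1, HB2, ccB2, dHB2, n, L, dWx, dWh, db);
  grads["lB2_Wx"] = Rcpp::wrap(dWx); grads["lB2_Wh"] = Rcpp::wrap(dWh);
  grads["lB2_b"] = Rcpp::wrap(mat(db));
  mat dXpB = lstm_backward(lB1_Wx, lB1_Wh, Xp, HB1, ccB1, dHB1, n, L, dWx, dWh, db);
  grads["lB1_Wx"] = Rcpp::wrap(dWx); grads["lB1_Wh"] = Rcpp::wrap(dWh);
  grads["lB1_b"] = Rcpp::wrap(mat(db));

  mat dA3 = to_samplemajor(dXpA + dXpB, n, L);
  mat dpre3 = dA3 % conv_to<mat>::from(pre3 > 0);
  grads["c3_W"] = Rcpp::wrap(mat(dpre3 * P2.t()));
  grads["c3_b"] = Rcpp::wrap(mat(sum(dpre3, 1)));
  mat dP2 = c3_W.t() * dpre3;
  if (training && drop > 0) dP2 %= D2;
  mat dA2(C2, n * L, fill::zeros);
  maxpool_s1_back(dA2, dP2, am2, n, L);

  mat dP1(P1.n_rows, P1.n_cols, fill::zeros);
  {
    int off = 0;
    for (int b = 0; b < n2; ++b) {
      mat dpre = dA2.rows(off, off + c2_c[b] - 1) %
        conv_to<mat>::from(pre2[b] > 0);
      grads["c2_W_" + std::to_string(b + 1)] = Rcpp::wrap(mat(dpre * col2[b].t()));
      grads["c2_b_" + std::to_string(b + 1)] = Rcpp::wrap(mat(sum(dpre, 1)));
      mat W = pget(params, "c2_W_" + std::to_string(b + 1));
      mat dcol = W.t() * dpre;
      col2im_same_add(dP1, dcol, n, L, c2_k[b]);
      off += c2_c[b];
    }
  }
  if (training && drop > 0) dP1 %= D1;
  mat dA1(C1, n * L, fill::zeros);
  maxpool_s1_back(dA1, dP1, am1, n, L);

  mat dI(E, n * L, fill::zeros);
  {
    int off = 0;
    for (int b = 0; b < n1; ++b) {
      mat dpre = dA1.rows(off, off + c1_c[b] - 1) %
        conv_to<mat>::from(pre1[b] > 0);
      grads["c1_W_" + std::to_string(b + 1)] = Rcpp::wrap(mat(dpre * col1[b].t()));
      grads["c1_b_" + std::to_string(b + 1)] = Rcpp::wrap(mat(sum(dpre, 1)));
      mat W = pget(params, "c1_W_" + std::to_string(b + 1));
      mat dcol = W.t() * dpre;
      col2im_same_add(dI, dcol, n, L, c1_k[b]);
      off += c1_c[b];
    }
  }

  grads["fuse_W"] = Rcpp::wrap(mat(X * dI.t()));
  grads["fuse_b"] = Rcpp::wrap(fuse_bias ? mat(sum(dI, 1))
                                         : mat(E, 1, fill::zeros));
  mat dX = fuse_W * dI;                          // 34E x n*L
  mat demb(442, E, fill::zeros);
  for (int s = 0; s < n; ++s)
    for (int j = 0; j < L; ++j) {
      const int cidx = s * L + j;
      for (int i = 0; i < LM; ++i) {
        const int code = codes(s, i + LM * j);
        if (code != 0)
          demb.row(code) += dX.submat(i * E, cidx, (i + 1) * E - 1, cidx).t();
      }
    }
  // pad vector (row 0) stays frozen at zero
  grads["emb"] = Rcpp::wrap(demb);

  return Rcpp::List::create(
    Rcpp::Named("yhat") = Rcpp::wrap(conv_to<vec>::from(yhat)),
    Rcpp::Named("loss") = loss,
    Rcpp::Named("grads") = grads);
}
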
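#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::rowvec;

// Dual-branch 1-D CNN -> maxpool(2,2) -> dropout -> channel concat -> BiLSTM
// -> global average pooling -> [late fusion concat] -> dense ReLU -> dropout
// -> softmax. Variant toggles drop branches, the BiLSTM, or the fused vector.
// Forward and reverse-mode gradients are implemented directly; sequences are
// processed at their true (unpadded) length so padding can never leak into
// pooling or the recurrent state.

namespace {

struct Spec {
  int E, ka, kb, F, H, D, C, fusion;
  bool use_a, use_b, use_bilstm;
  double dropout;
};

Spec parse_spec(const List &s) {
  Spec sp;
  sp.E = as<int>(s["embed_dim"]);
  sp.ka = as<int>(s["kernel_a"]);
  sp.kb = as<int>(s["kernel_b"]);
  sp.F = as<int>(s["filters"]);
  sp.H = as<int>(s["bilstm_units"]);
  sp.D = as<int>(s["dense_units"]);
  sp.C = as<int>(s["n_classes"]);
  sp.fusion = as<int>(s["fusion_dim"]);
  sp.use_a = as<bool>(s["use_branch_a"]);
  sp.use_b = as<bool>(s["use_branch_b"]);
  sp.use_bilstm = as<bool>(s["use_bilstm"]);
  sp.dropout = as<double>(s["dropout"]);
  return sp;
}

// "same" zero-padded im2col for an odd kernel k: row t holds the k stacked
// input rows centred on t.
mat im2col(const mat &X, int k) {
  const int T = X.n_rows, E = X.n_cols, h = (k - 1) / 2;
  mat M(T, k * E, arma::fill::zeros);
  for (int dt = 0; dt < k; ++dt) {
    const int off = dt - h;
    const int lo = std::max(0, -off), hi = std::min(T, T - off);
    if (hi > lo)
      M.submat(lo, dt * E, hi - 1, (dt + 1) * E - 1) =
          X.rows(lo + off, hi + off - 1);
  }
  return M;
}

void col2im_add(mat &dX, const mat &dM, int k) {
  const int T = dX.n_rows, E = dX.n_cols, h = (k - 1) / 2;
  for (int dt = 0; dt < k; ++dt) {
    const int off = dt - h;
    const int lo = std::max(0, -off), hi = std::min(T, T - off);
    if (hi > lo)
      dX.rows(lo + off, hi + off - 1) +=
          dM.submat(lo, dt * E, hi - 1, (dt + 1) * E - 1);
  }
}

struct LstmCache {
  mat I, Fg, G, O, Cs, Hs;  // Tz x H each; gate order [i | f | g | o]
};

LstmCache lstm_fwd(const mat &Z, const mat &W, const mat &U, const rowvec &b,
                   bool reverse) {
  const int Tz = Z.n_rows, H = U.n_rows;
  LstmCache c;
  c.I.set_size(Tz, H);
  c.Fg.set_size(Tz, H);
  c.G.set_size(Tz, H);
  c.O.set_size(Tz, H);
  c.Cs.set_size(Tz, H);
  c.Hs.set_size(Tz, H);
  rowvec h(H, arma::fill::zeros), cs(H, arma::fill::zeros);
  mat ZW = Z * W;  // hoist the input contribution out of the recurrence
  ZW.each_row() += b;
  for (int step = 0; step < Tz; ++step) {
    const int t = reverse ? Tz - 1 - step : step;
    rowvec g = ZW.row(t) + h * U;
    rowvec gi = 1.0 / (1.0 + arma::exp(-g.cols(0, H - 1)));
    rowvec gf = 1.0 / (1.0 + arma::exp(-g.cols(H, 2 * H - 1)));
    rowvec gg = arma::tanh(g.cols(2 * H, 3 * H - 1));
    rowvec go = 1.0 / (1.0 + arma::exp(-g.cols(3 * H, 4 * H - 1)));
    cs = gf % cs + gi % gg;
    h = go % arma::tanh(cs);
    c.I.row(t) = gi;
    c.Fg.row(t) = gf;
    c.G.row(t) = gg;
    c.O.row(t) = go;
    c.Cs.row(t) = cs;
    c.Hs.row(t) = h;
  }
  return c;
}

void lstm_bwd(const mat &Z, const mat &W, const mat &U, const LstmCache &c,
              const mat &dH, bool reverse, mat &dW, mat &dU, rowvec &db,
              mat &dZ) {
  const int Tz = Z.n_rows, H = U.n_rows;
  rowvec dh_next(H, arma::fill::zeros), dc(H, arma::fill::zeros);
  mat PG(Tz, 4 * H);          // pre-activation gate gradients
  mat Hprev(Tz, H, arma::fill::zeros);  // hidden state feeding step t
  for (int step = Tz - 1; step >= 0; --step) {
    const int t = reverse ? Tz - 1 - step : step;
    rowvec cprev(H, arma::fill::zeros);
    if (step > 0) {
      const int tp = reverse ? Tz - step : step - 1;
      cprev = c.Cs.row(tp);
      Hprev.row(t) = c.Hs.row(tp);
    }
    const rowvec gi = c.I.row(t), gf = c.Fg.row(t), gg = c.G.row(t),
                 go = c.O.row(t), cs = c.Cs.row(t);
    const rowvec th = arma::tanh(cs);
    rowvec dh = dH.row(t) + dh_next;
    rowvec dgo = dh % th;
    dc += dh % go % (1.0 - th % th);
    rowvec dgi = dc % gg, dgg = dc % gi, dgf = dc % cprev;
    rowvec dcprev = dc % gf;
    rowvec pg(4 * H);
    pg.cols(0, H - 1) = dgi % gi % (1.0 - gi);
    pg.cols(H, 2 * H - 1) = dgf % gf % (1.0 - gf);
    pg.cols(2 * H, 3 * H - 1) = dgg % (1.0 - gg % gg);
    pg.cols(3 * H, 4 * H - 1) = dgo % go % (1.0 - go);
    PG.row(t) = pg;
    dh_next = pg * U.t();
    dc = dcprev;
  }
  dW += Z.t() * PG;
  dU += Hprev.t() * PG;
  db += arma::sum(PG, 0);
  dZ += PG * W.t();
}

struct Net {
  Spec sp;
  bool has_emb = false, has_proj = false;
  mat emb, Wp, Wa, Wb, Wf, Uf, Wr, Ur, Wd, Ws;
  rowvec ba, bb, bf, br, bd, bs;
  // gradient accumulators (mirrors of the above)
  mat g_emb, g_Wp, g_Wa, g_Wb, g_Wf, g_Uf, g_Wr, g_Ur, g_Wd, g_Ws;
  rowvec g_ba, g_bb, g_bf, g_br, g_bd, g_bs;

  bool conv() const { return sp.use_a || sp.use_b; }
  int lstm_in() const {
    return conv() ? sp.F * ((sp.use_a ? 1 : 0) + (sp.use_b ? 1 : 0)) : sp.E;
  }
  int gap_dim() const { return sp.use_bilstm ? 2 * sp.H : lstm_in(); }

  void load(const List &p, const List &s) {
    sp = parse_spec(s);
    has_emb = p.containsElementNamed("emb");
    if (has_emb) emb = as<mat>(p["emb"]);
    has_proj = p.containsElementNamed("Wp");
    if (has_proj) Wp = as<mat>(p["Wp"]);
    if (sp.use_a) {
      Wa = as<mat>(p["Wa"]);
      ba = as<rowvec>(p["ba"]);
    }
    if (sp.use_b) {
      Wb = as<mat>(p["Wb"]);
      bb = as<rowvec>(p["bb"]);
    }
    if (sp.use_bilstm) {
      Wf = as<mat>(p["Wf"]);
      Uf = as<mat>(p["Uf"]);
      bf = as<rowvec>(p["bf"]);
      Wr = as<mat>(p["Wr"]);
      Ur = as<mat>(p["Ur"]);
      br = as<rowvec>(p["br"]);
    }
    Wd = as<mat>(p["Wd"]);
    bd = as<rowvec>(p["bd"]);
    Ws = as<mat>(p["Ws"]);
    bs = as<rowvec>(p["bs"]);
  }

  void zero_grads() {
    if (has_emb) g_emb.zeros(emb.n_rows, emb.n_cols);
    if (has_proj) g_Wp.zeros(Wp.n_rows, Wp.n_cols);
    if (sp.use_a) {
      g_Wa.zeros(Wa.n_rows, Wa.n_cols);
      g_ba.zeros(ba.n_elem);
    }
    if (sp.use_b) {
      g_Wb.zeros(Wb.n_rows, Wb.n_cols);
      g_bb.zeros(bb.n_elem);
    }
    if (sp.use_bilstm) {
      g_Wf.zeros(Wf.n_rows, Wf.n_cols);
      g_Uf.zeros(Uf.n_rows, Uf.n_cols);
      g_bf.zeros(bf.n_elem);
      g_Wr.zeros(Wr.n_rows, Wr.n_cols);
      g_Ur.zeros(Ur.n_rows, Ur.n_cols);
      g_br.zeros(br.n_elem);
    }
    g_Wd.zeros(Wd.n_rows, Wd.n_cols);
    g_bd.zeros(bd.n_elem);
    g_Ws.zeros(Ws.n_rows, Ws.n_cols);
    g_bs.zeros(bs.n_elem);
  }

  void scale_grads(double f) {
    if (has_emb) g_emb *= f;
    if (has_proj) g_Wp *= f;
    if (sp.use_a) {
      g_Wa *= f;
      g_ba *= f;
    }
    if (sp.use_b) {
      g_Wb *= f;
      g_bb *= f;
    }
    if (sp.use_bilstm) {
      g_Wf *= f;
      g_Uf *= f;
      g_bf *= f;
      g_Wr *= f;
      g_Ur *= f;
      g_br *= f;
    }
    g_Wd *= f;
    g_bd *= f;
    g_Ws *= f;
    g_bs *= f;
  }

  List grads_list() const {
    List g;
    if (has_emb) g["emb"] = g_emb;
    if (has_proj) g["Wp"] = g_Wp;
    if (sp.use_a) {
      g["Wa"] = g_Wa;
      g["ba"] = g_ba;
    }
    if (sp.use_b) {
      g["Wb"] = g_Wb;
      g["bb"] = g_bb;
    }
    if (sp.use_bilstm) {
      g["Wf"] = g_Wf;
      g["Uf"] = g_Uf;
      g["bf"] = g_bf;
      g["Wr"] = g_Wr;
      g["Ur"] = g_Ur;
      g["br"] = g_br;
    }
    g["Wd"] = g_Wd;
    g["bd"] = g_bd;
    g["Ws"] = g_Ws;
    g["bs"] = g_bs;
    return g;
  }

  // mode 0: inference; mode 1: cross-entropy gradient for label y;
  // mode 2: gradient of the target-class logit (dropout off, for attribution).
  // dX (if non-null) receives the gradient w.r.t. the raw input matrix X0.
  void pass(const arma::uvec *tokens, const mat *Xin, const rowvec *fused,
            int mode, int y, std::mt19937_64 *rng, rowvec &probs,
            rowvec &logits, double &loss, mat *dXout) {
    const double p_drop = (mode == 1) ? sp.dropout : 0.0;
    const double keep = 1.0 - p_drop;

    mat X0 = tokens ? emb.rows(*tokens) : *Xin;
    mat X = has_proj ? mat(X0 * Wp) : X0;
    const int T = X.n_rows;
    if (conv() && T < 2) stop("sequence too short for pooling (length < 2)");

    auto draw_mask = [&](int r, int c) {
      mat Mk(r, c, arma::fill::ones);
      if (p_drop > 0.0 && rng) {
        std::uniform_real_distribution<double> unif(0.0, 1.0);
        for (int i = 0; i < r; ++i)
          for (int j = 0; j < c; ++j)
            Mk(i, j) = (unif(*rng) < keep) ? 1.0 / keep : 0.0;
      }
      return Mk;
    };

    // convolution branches
    const int T2 = conv() ? T / 2 : T;
    mat Ma, Aa, Pa, Da, Mb, Ab, Pb, Db;
    arma::umat argA, argB;
    auto branch_fwd = [&](const mat &W, const rowvec &b, int k, mat &M, mat &A,
                          mat &P, arma::umat &arg) {
      M = im2col(X, k);
      A = M * W;
      A.each_row() += b;
      mat Hr = arma::clamp(A, 0.0, arma::datum::inf);
      P.set_size(T2, sp.F);
      arg.set_size(T2, sp.F);
      for (int i = 0; i < T2; ++i) {
        for (int f = 0; f < sp.F; ++f) {
          const double v0 = Hr(2 * i, f), v1 = Hr(2 * i + 1, f);
          if (v0 >= v1) {
            P(i, f) = v0;
            arg(i, f) = 0;
          } else {
            P(i, f) = v1;
            arg(i, f) = 1;
          }
        }
      }
    };
    mat Z;
    if (conv()) {
      std::vector<mat> parts;
      if (sp.use_a) {
        branch_fwd(Wa, ba, sp.ka, Ma, Aa, Pa, argA);
        Da = draw_mask(T2, sp.F);
        parts.push_back(Pa % Da);
      }
      if (sp.use_b) {
        branch_fwd(Wb, bb, sp.kb, Mb, Ab, Pb, argB);
        Db = draw_mask(T2, sp.F);
        parts.push_back(Pb % Db);
      }
      Z = parts.size() == 2 ? mat(arma::join_rows(parts[0], parts[1]))
                            : parts[0];
    } else {
      Z = X;
    }

    // BiLSTM
    LstmCache cf, cr;
    mat Gin;
    if (sp.use_bilstm) {
      cf = lstm_fwd(Z, Wf, Uf, bf, false);
      cr = lstm_fwd(Z, Wr, Ur, br, true);
      Gin = arma::join_rows(cf.Hs, cr.Hs);
    } else {
      Gin = Z;
    }

    // global average pooling + late fusion + head
    rowvec gvec = arma::mean(Gin, 0);
    rowvec h0 = (sp.fusion > 0 && fused) ? rowvec(arma::join_rows(gvec, *fused))
                                         : gvec;
    rowvec ad = h0 * Wd + bd;
    rowvec zd = arma::clamp(ad, 0.0, arma::datum::inf);
    mat Ddense = draw_mask(1, sp.D);
    rowvec zdd = zd % Ddense.row(0);
    logits = zdd * Ws + bs;
    rowvec sh = logits - logits.max();
    rowvec ex = arma::exp(sh);
    probs = ex / arma::accu(ex);
    loss = (mode == 1) ? -std::log(std::max(probs(y), 1e-12)) : 0.0;

    if (mode == 0) return;

    // ---- backward ----
    const bool pg = (mode == 1);  // accumulate parameter gradients?
    rowvec dlog(sp.C, arma::fill::zeros);
    if (mode == 1) {
      dlog = probs;
      dlog(y) -= 1.0;
    } else {
      dlog(y) = 1.0;  // y doubles as target class for mode 2
    }
    if (pg) {
      g_Ws += zdd.t() * dlog;
      g_bs += dlog;
    }
    rowvec dzd = (dlog * Ws.t()) % Ddense.row(0);
    for (int j = 0; j < sp.D; ++j)
      if (ad(j) <= 0.0) dzd(j) = 0.0;
    if (pg) {
      g_Wd += h0.t() * dzd;
      g_bd += dzd;
    }
    rowvec dh0 = dzd * Wd.t();
    rowvec dg = dh0.cols(0, gap_dim() - 1);

    mat dGin(Gin.n_rows, Gin.n_cols);
    dGin.each_row() = dg / (double)Gin.n_rows;

    mat dZ(Z.n_rows, Z.n_cols, arma::fill::zeros);
    if (sp.use_bilstm) {
      mat dHf = dGin.cols(0, sp.H - 1), dHr = dGin.cols(sp.H, 2 * sp.H - 1);
      mat tWf(Wf.n_rows, Wf.n_cols, arma::fill::zeros),
          tUf(Uf.n_rows, Uf.n_cols, arma::fill::zeros);
      rowvec tbf(bf.n_elem, arma::fill::zeros);
      lstm_bwd(Z, Wf, Uf, cf, dHf, false, tWf, tUf, tbf, dZ);
      mat tWr(Wr.n_rows, Wr.n_cols, arma::fill::zeros),
          tUr(Ur.n_rows, Ur.n_cols, arma::fill::zeros);
      rowvec tbr(br.n_elem, arma::fill::zeros);
      lstm_bwd(Z, Wr, Ur, cr, dHr, true, tWr, tUr, tbr, dZ);
      if (pg) {
        g_Wf += tWf;
        g_Uf += tUf;
        g_bf += tbf;
        g_Wr += tWr;
        g_Ur += tUr;
        g_br += tbr;
      }
    } else {
      dZ = dGin;
    }

    mat dX(T, sp.E, arma::fill::zeros);
    if (conv()) {
      int col0 = 0;
      auto branch_bwd = [&](const mat &W, int k, const mat &M, const mat &A,
                            const arma::umat &arg, const mat &Dm, mat &gW,
                            rowvec &gb) {
        mat dP = dZ.cols(col0, col0 + sp.F - 1) % Dm;
        col0 += sp.F;
        mat dA(T, sp.F, arma::fill::zeros);
        for (int i = 0; i < T2; ++i)
          for (int f = 0; f < sp.F; ++f)
            dA(2 * i + (int)arg(i, f), f) = dP(i, f);
        for (int t = 0; t < T; ++t)
          for (int f = 0; f < sp.F; ++f)
            if (A(t, f) <= 0.0) dA(t, f) = 0.0;
        if (pg) {
          gW += M.t() * dA;
          gb += arma::sum(dA, 0);
        }
        mat dM = dA * W.t();
        col2im_add(dX, dM, k);
      };
      if (sp.use_a) branch_bwd(Wa, sp.ka, Ma, Aa, argA, Da, g_Wa, g_ba);
      if (sp.use_b) branch_bwd(Wb, sp.kb, Mb, Ab, argB, Db, g_Wb, g_bb);
    } else {
      dX = dZ;
    }

    mat dX0;
    if (has_proj) {
      if (pg) g_Wp += X0.t() * dX;
      dX0 = dX * Wp.t();
    } else {
      dX0 = dX;
    }
    if (tokens && pg) {
      for (int t = 0; t < T; ++t) g_emb.row((*tokens)(t)) += dX0.row(t);
    }
    if (dXout) *dXout = dX0;
  }
};

arma::uvec tokens0(const IntegerVector &tk) {
  arma::uvec u(tk.size());
  for (int i = 0; i < tk.size(); ++i) {
    if (tk[i] < 1) stop("token indices must be >= 1");
    u(i) = (arma::uword)(tk[i] - 1);
  }
  return u;
}

}  // namespace

// [[Rcpp::export]]
List cpp_batch_grad(List params, List spec, List tokens,
                    Nullable<NumericMatrix> fused, IntegerVector y, int seed) {
  Net net;
  net.load(params, spec);
  net.zero_grads();
  const int n = tokens.size();
  mat fmat;
  const bool has_f = fused.isNotNull();
  if (has_f) fmat = as<mat>(fused.get());
  std::mt19937_64 rng((uint64_t)seed);
  mat probs(n, net.sp.C);
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    arma::uvec tk = tokens0(tokens[i]);
    rowvec fr;
    if (has_f) fr = fmat.row(i);
    rowvec pr, lg;
    double l = 0.0;
    net.pass(&tk, nullptr, has_f ? &fr : nullptr, 1, y[i], &rng, pr, lg, l,
             nullptr);
    probs.row(i) = pr;
    total += l;
  }
  net.scale_grads(1.0 / n);
  return List::create(_["loss"] = total / n, _["probs"] = probs,
                      _["grads"] = net.grads_list());
}

// [[Rcpp::export]]
List cpp_predict(List params, List spec, List tokens,
                 Nullable<NumericMatrix> fused) {
  Net net;
  net.load(params, spec);
  const int n = tokens.size();
  mat fmat;
  const bool has_f = fused.isNotNull();
  if (has_f) fmat = as<mat>(fused.get());
  mat probs(n, net.sp.C), logits(n, net.sp.C);
  for (int i = 0; i < n; ++i) {
    arma::uvec tk = tokens0(tokens[i]);
    rowvec fr;
    if (has_f) fr = fmat.row(i);
    rowvec pr, lg;
    double l = 0.0;
    net.pass(&tk, nullptr, has_f ? &fr : nullptr, 0, 0, nullptr, pr, lg, l,
             nullptr);
    probs.row(i) = pr;
    logits.row(i) = lg;
  }
  return List::create(_["probs"] = probs, _["logits"] = logits);
}

// [[Rcpp::export]]
List cpp_forward_X(List params, List spec, arma::mat X,
                   Nullable<NumericVector> fused) {
  Net net;
  net.load(params, spec);
  rowvec fr;
  const bool has_f = fused.isNotNull();
  if (has_f) fr = rowvec(as<arma::vec>(fused.get()).t());
  rowvec pr, lg;
  double l = 0.0;
  net.pass(nullptr, &X, has_f ? &fr : nullptr, 0, 0, nullptr, pr, lg, l,
           nullptr);
  return List::create(_["probs"] = pr, _["logits"] = lg);
}

// [[Rcpp::export]]
List cpp_input_grad(List params, List spec, arma::mat X,
                    Nullable<NumericVector> fused, int target) {
  Net net;
  net.load(params, spec);
  net.zero_grads();
  rowvec fr;
  const bool has_f = fused.isNotNull();
  if (has_f) fr = rowvec(as<arma::vec>(fused.get()).t());
  rowvec pr, lg;
  double l = 0.0;
  mat dX;
  net.pass(nullptr, &X, has_f ? &fr : nullptr, 2, target, nullptr, pr, lg, l,
           &dX);
  return List::create(_["logit"] = lg((arma::uword)target), _["logits"] = lg,
                      _["probs"] = pr, _["dX"] = dX);
}
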
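// Transformer encoder-decoder core for next-prescription drug-set prediction.
//
// Layout of a sample sequence: position 0 is a static token (sex + age),
// positions 1..T are week tokens for the input window.  Missing weeks are
// excluded from every attention computation via the attention mask; their
// stored values are never read, so model output is invariant to whatever
// sits in masked slots.
//
// All parameters travel as a named list of matrices; biases are 1 x d.
// No RNG lives here: batch orders and initial weights are generated in R.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <map>
#include <set>
#include <string>
#include <vector>

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::rowvec;
using arma::cube;

static const double LN_EPS  = 1e-5;
static const double P_EPS   = 1e-7;
static const double NEG_INF = -1e30;

typedef std::map<std::string, mat> PMap;

struct Cfg {
  int d, H, dh, Lenc, Ldec, dff, T, S, Cn, Cc, N;
  std::vector<int> K;   // cardinality per categorical channel
};

static Cfg read_cfg(const List& cl) {
  Cfg c;
  c.d    = as<int>(cl["hidden"]);
  c.H    = as<int>(cl["heads"]);
  c.Lenc = as<int>(cl["encoderLayers"]);
  c.Ldec = as<int>(cl["decoderLayers"]);
  c.dff  = as<int>(cl["ffDim"]);
  c.T    = as<int>(cl["windowWeeks"]);
  c.Cn   = as<int>(cl["nNumeric"]);
  c.Cc   = as<int>(cl["nCategorical"]);
  c.N    = as<int>(cl["nDrugs"]);
  c.S    = c.T + 1;
  if (c.d % c.H != 0) stop("hidden dimension must be divisible by the number of heads");
  c.dh = c.d / c.H;
  if (c.Cc > 0) {
    IntegerVector kk = cl["catLevels"];
    for (int i = 0; i < kk.size(); ++i) c.K.push_back(kk[i]);
  }
  return c;
}

static PMap read_params(const List& pl) {
  PMap p;
  CharacterVector nm = pl.names();
  for (int i = 0; i < pl.size(); ++i)
    p[as<std::string>(nm[i])] = as<mat>(pl[i]);
  return p;
}

static List params_to_list(const PMap& p) {
  List out;
  for (PMap::const_iterator it = p.begin(); it != p.end(); ++it)
    out[it->first] = wrap(it->second);
  return out;
}

static PMap zeros_like(const PMap& p) {
  PMap g;
  for (PMap::const_iterator it = p.begin(); it != p.end(); ++it)
    g[it->first] = mat(it->second.n_rows, it->second.n_cols, arma::fill::zeros);
  return g;
}

struct Data {
  cube numv, numm, catv, drugs;
  mat weekmask;       // T x n
  vec sex, age;       // n
  mat target;         // N x n
  int n;
};

static Data read_data(const List& dl) {
  Data d;
  d.numv     = as<cube>(dl["numv"]);
  d.numm     = as<cube>(dl["numm"]);
  d.catv     = as<cube>(dl["catv"]);
  d.drugs    = as<cube>(dl["drugs"]);
  d.weekmask = as<mat>(dl["weekmask"]);
  d.sex      = as<vec>(dl["sex"]);
  d.age      = as<vec>(dl["age"]);
  d.target   = as<mat>(dl["target"]);
  d.n        = d.weekmask.n_cols;
  return d;
}

// ---------------------------------------------------------------- layer norm

struct LNCache { mat xhat; vec istd; };

static mat ln_fwd(const mat& X, const mat& g, const mat& b, LNCache& cc) {
  vec mu = arma::mean(X, 1);
  mat Xc = X.each_col() - mu;
  vec vv = arma::mean(arma::square(Xc), 1);
  cc.istd = 1.0 / arma::sqrt(vv + LN_EPS);
  Xc.each_col() %= cc.istd;
  cc.xhat = Xc;
  mat Y = Xc.each_row() % g.row(0);
  Y.each_row() += b.row(0);
  return Y;
}

static mat ln_bwd(const mat& dY, const mat& g, const LNCache& cc, mat& dg, mat& db) {
  dg += arma::sum(dY % cc.xhat, 0);
  db += arma::sum(dY, 0);
  mat dxh = dY.each_row() % g.row(0);
  vec m1 = arma::mean(dxh, 1);
  vec m2 = arma::mean(dxh % cc.xhat, 1);
  mat dX = dxh;
  dX.each_col() -= m1;
  dX -= cc.xhat.each_col() % m2;
  dX.each_col() %= cc.istd;
  return dX;
}

// ----------------------------------------------------------------- attention

struct AttnCache { mat Q, K, V, C; std::vector<mat> P; };

static mat attn_fwd(const mat& Aq, const mat& Akv, PMap& p, const std::string& pre,
                    const vec& keymask, bool causal, const Cfg& c, AttnCache& ac) {
  ac.Q = Aq * p[pre + "Wq"];  ac.Q.each_row() += p[pre + "bq"].row(0);
  ac.K = Akv * p[pre + "Wk"]; ac.K.each_row() += p[pre + "bk"].row(0);
  ac.V = Akv * p[pre + "Wv"]; ac.V.each_row() += p[pre + "bv"].row(0);
  int Sq = Aq.n_rows, Sk = Akv.n_rows;
  ac.P.assign(c.H, mat());
  ac.C.set_size(Sq, c.d);
  double sc = 1.0 / std::sqrt((double)c.dh);
  rowvec madd(Sk, arma::fill::zeros);
  for (int j = 0; j < Sk; ++j)
    if (keymask(j) < 0.5) madd(j) = NEG_INF;
  mat cmask;
  if (causal) {
    cmask.zeros(Sq, Sk);
    for (int i = 0; i < Sq; ++i)
      for (int j = i + 1; j < Sk; ++j) cmask(i, j) = NEG_INF;
  }
  for (int h = 0; h < c.H; ++h) {
    arma::span cs(h * c.dh, (h + 1) * c.dh - 1);
    mat Sm = ac.Q.cols(cs) * ac.K.cols(cs).t() * sc;
    Sm.each_row() += madd;
    if (causal) Sm += cmask;
    vec mx = arma::max(Sm, 1);
    mat P = arma::exp(Sm.each_col() - mx);
    vec se = arma::sum(P, 1);
    P.each_col() /= se;
    ac.P[h] = P;
    ac.C.cols(cs) = P * ac.V.cols(cs);
  }
  mat O = ac.C * p[pre + "Wo"];
  O.each_row() += p[pre + "bo"].row(0);
  return O;
}

static void attn_bwd(const mat& dO, const mat& Aq, const mat& Akv, PMap& p, PMap& g,
                     const std::string& pre, const Cfg& c, const AttnCache& ac,
                     mat& dAq, mat& dAkv) {
  g[pre + "Wo"] += ac.C.t() * dO;
  g[pre + "bo"] += arma::sum(dO, 0);
  mat dC = dO * p[pre + "Wo"].t();
  mat dQ(ac.Q.n_rows, ac.Q.n_cols, arma::fill::zeros);
  mat dK(ac.K.n_rows, ac.K.n_cols, arma::fill::zeros);
  mat dV(ac.V.n_rows, ac.V.n_cols, arma::fill::zeros);
  double sc = 1.0 / std::sqrt((double)c.dh);
  for (int h = 0; h < c.H; ++h) {
    arma::span cs(h * c.dh, (h + 1) * c.dh - 1);
    mat dCh = dC.cols(cs);
    const mat& P = ac.P[h];
    mat Qh = ac.Q.cols(cs), Kh = ac.K.cols(cs), Vh = ac.V.cols(cs);
    mat dP = dCh * Vh.t();
    dV.cols(cs) = P.t() * dCh;
    vec dot = arma::sum(P % dP, 1);
    mat dS = P % (dP.each_col() - dot);  // zero wherever attention was masked
    dS *= sc;
    dQ.cols(cs) = dS * Kh;
    dK.cols(cs) = dS.t() * Qh;
  }
  g[pre + "Wq"] += Aq.t() * dQ;  g[pre + "bq"] += arma::sum(dQ, 0);
  g[pre + "Wk"] += Akv.t() * dK; g[pre + "bk"] += arma::sum(dK, 0);
  g[pre + "Wv"] += Akv.t() * dV; g[pre + "bv"] += arma::sum(dV, 0);
  dAq  += dQ * p[pre + "Wq"].t();
  dAkv += dK * p[pre + "Wk"].t() + dV * p[pre + "Wv"].t();
}

// ------------------------------------------------- pre-LN transformer block

struct BlockCache {
  LNCache ln1; mat a; AttnCache at; mat x_mid;
  LNCache ln2; mat b; mat hpre; mat r;
};

static mat block_fwd(const mat& X, const mat& Akv_ext, bool cross, PMap& p,
                     const std::string& pre, const vec& keymask, bool causal,
                     const Cfg& c, BlockCache& bc) {
  bc.a = ln_fwd(X, p[pre + "ln1_g"], p[pre + "ln1_b"], bc.ln1);
  const mat& Akv = cross ? Akv_ext : bc.a;
  mat O = attn_fwd(bc.a, Akv, p, pre, keymask, causal, c, bc.at);
  bc.x_mid = X + O;
  bc.b = ln_fwd(bc.x_mid, p[pre + "ln2_g"], p[pre + "ln2_b"], bc.ln2);
  bc.hpre = bc.b * p[pre + "W1"];
  bc.hpre.each_row() += p[pre + "b1"].row(0);
  bc.r = bc.hpre;
  bc.r.elem(arma::find(bc.r < 0.0)).zeros();
  mat G = bc.r * p[pre + "W2"];
  G.each_row() += p[pre + "b2"].row(0);
  return bc.x_mid + G;
}

static mat block_bwd(const mat& dY, bool cross, const mat& Akv_ext, mat& dAkv_ext,
                     PMap& p, PMap& g, const std::string& pre, const Cfg& c,
                     const BlockCache& bc) {
  g[pre + "W2"] += bc.r.t() * dY;
  g[pre + "b2"] += arma::sum(dY, 0);
  mat dR = dY * p[pre + "W2"].t();
  dR.elem(arma::find(bc.hpre <= 0.0)).zeros();
  g[pre + "W1"] += bc.b.t() * dR;
  g[pre + "b1"] += arma::sum(dR, 0);
  mat dB = dR * p[pre + "W1"].t();
  mat dXmid = dY + ln_bwd(dB, p[pre + "ln2_g"], bc.ln2, g[pre + "ln2_g"], g[pre + "ln2_b"]);
  mat dA(bc.a.n_rows, bc.a.n_cols, arma::fill::zeros);
  if (cross) {
    attn_bwd(dXmid, bc.a, Akv_ext, p, g, pre, c, bc.at, dA, dAkv_ext);
  } else {
    mat dAkv(bc.a.n_rows, bc.a.n_cols, arma::fill::zeros);
    attn_bwd(dXmid, bc.a, bc.a, p, g, pre, c, bc.at, dA, dAkv);
    dA += dAkv;
  }
  return dXmid + ln_bwd(dA, p[pre + "ln1_g"], bc.ln1, g[pre + "ln1_g"], g[pre + "ln1_b"]);
}

// ----------------------------------------------------------------- embedding

static void embed_fwd(PMap& p, const Data& dt, int i, const Cfg& c, mat& tok, vec& mask) {
  tok.zeros(c.S, c.d);
  mask.zeros(c.S);
  int sx = (int)dt.sex(i) - 1;
  double ag = dt.age(i);
  tok.row(0) = p["sex_emb"].row(sx) + ag * p["age_w"].row(0) + p["age_b"].row(0);
  mask(0) = 1.0;
  const mat& pe = p["pe"];
  for (int t = 0; t < c.T; ++t) {
    rowvec v = pe.row(t + 1);
    for (int ch = 0; ch < c.Cn; ++ch)
      if (dt.numm(ch, t, i) > 0.5)
        v += dt.numv(ch, t, i) * p["num_w"].col(ch).t() + p["num_b"].col(ch).t();
    for (int ch = 0; ch < c.Cc; ++ch) {
      int k = (int)dt.catv(ch, t, i);
      if (k > 0)
        v += p["cat" + std::to_string(ch + 1) + "_emb"].row(k - 1);
    }
    for (int j = 0; j < c.N; ++j)
      if (dt.drugs(j, t, i) > 0.5) v += p["drug_emb"].row(j);
    tok.row(t + 1) = v;
    mask(t + 1) = dt.weekmask(t, i) > 0.5 ? 1.0 : 0.0;
  }
}

static void embed_bwd(PMap& p, PMap& g, const mat& dTok, const Data& dt, int i, const Cfg& c) {
  int sx = (int)dt.sex(i) - 1;
  double ag = dt.age(i);
  g["sex_emb"].row(sx) += dTok.row(0);
  g["age_w"] += ag * dTok.row(0);
  g["age_b"] += dTok.row(0);
  for (int t = 0; t < c.T; ++t) {
    rowvec dv = dTok.row(t + 1);
    for (int ch = 0; ch < c.Cn; ++ch)
      if (dt.numm(ch, t, i) > 0.5) {
        g["num_w"].col(ch) += dt.numv(ch, t, i) * dv.t();
        g["num_b"].col(ch) += dv.t();
      }
    for (int ch = 0; ch < c.Cc; ++ch) {
      int k = (int)dt.catv(ch, t, i);
      if (k > 0)
        g["cat" + std::to_string(ch + 1) + "_emb"].row(k - 1) += dv;
    }
    for (int j = 0; j < c.N; ++j)
      if (dt.drugs(j, t, i) > 0.5) g["drug_emb"].row(j) += dv;
  }
}

// ------------------------------------------------------------------- encoder

struct EncCache {
  mat tok; vec mask;
  std::vector<BlockCache> B;
  LNCache lnf; mat enc;
};

static void encode_fwd(PMap& p, const mat& tok, const vec& mask, bool causal,
                       const Cfg& c, EncCache& ec) {
  if (arma::accu(mask) < 0.5) stop("all positions are masked: nothing to attend to");
  ec.tok = tok;
  ec.mask = mask;
  ec.B.assign(c.Lenc, BlockCache());
  mat x = tok;
  for (int l = 0; l < c.Lenc; ++l)
    x = block_fwd(x, x, false, p, "enc" + std::to_string(l + 1) + "_", mask, causal, c, ec.B[l]);
  ec.enc = ln_fwd(x, p["enc_lnf_g"], p["enc_lnf_b"], ec.lnf);
}

static mat encode_bwd(PMap& p, PMap& g, const mat& dEnc, const Cfg& c, const EncCache& ec) {
  mat dx = ln_bwd(dEnc, p["enc_lnf_g"], ec.lnf, g["enc_lnf_g"], g["enc_lnf_b"]);
  mat dummy;
  for (int l = c.Lenc - 1; l >= 0; --l)
    dx = block_bwd(dx, false, dummy, dummy, p, g, "enc" + std::to_string(l + 1) + "_", c, ec.B[l]);
  return dx;
}

// ------------------------------------------------------------------- decoder

struct DecCache {
  mat q0;
  std::vector<BlockCache> B;
  LNCache lnf; mat u;
  rowvec z, s;
};

static void decode_fwd(PMap& p, const Data& dt, int i, const mat& enc, const vec& mask,
                       const Cfg& c, DecCache& dc) {
  int sx = (int)dt.sex(i) - 1;
  double ag = dt.age(i);
  dc.q0 = p["query"].row(0) + p["pe"].row(c.T + 1) + p["sex_emb"].row(sx)
          + ag * p["age_w"].row(0) + p["age_b"].row(0);
  mat q = dc.q0;
  dc.B.assign(c.Ldec, BlockCache());
  for (int l = 0; l < c.Ldec; ++l)
    q = block_fwd(q, enc, true, p, "dec" + std::to_string(l + 1) + "_", mask, false, c, dc.B[l]);
  dc.u = ln_fwd(q, p["dec_lnf_g"], p["dec_lnf_b"], dc.lnf);
  dc.z = dc.u.row(0) * p["out_W"] + p["out_b"].row(0);
  dc.s = 1.0 / (1.0 + arma::exp(-dc.z));
}

static mat decode_bwd(PMap& p, PMap& g, const rowvec& dz, const Data& dt, int i,
                      const mat& enc, const Cfg& c, const DecCache& dc) {
  g["out_W"] += dc.u.row(0).t() * dz;
  g["out_b"] += dz;
  mat dU = dz * p["out_W"].t();
  mat dq = ln_bwd(dU, p["dec_lnf_g"], dc.lnf, g["dec_lnf_g"], g["dec_lnf_b"]);
  mat dEnc(enc.n_rows, enc.n_cols, arma::fill::zeros);
  for (int l = c.Ldec - 1; l >= 0; --l)
    dq = block_bwd(dq, true, enc, dEnc, p, g, "dec" + std::to_string(l + 1) + "_", c, dc.B[l]);
  g["query"] += dq;
  int sx = (int)dt.sex(i) - 1;
  g["sex_emb"].row(sx) += dq.row(0);
  g["age_w"] += dt.age(i) * dq;
  g["age_b"] += dq;
  return dEnc;
}

// ---------------------------------------------------------------- focal loss

// returns the loss term; dz_out receives dLoss/dlogit
static double focal_term(double pprob, double y, double gamma, double a1, double a0,
                         double& dz_out) {
  double pt  = (y > 0.5) ? pprob : 1.0 - pprob;
  double at  = (y > 0.5) ? a1 : a0;
  double ptc = std::min(std::max(pt, P_EPS), 1.0 - P_EPS);
  double omp = 1.0 - ptc;
  double loss = -at * std::pow(omp, gamma) * std::log(ptc);
  double dldpt = at * (gamma * std::pow(omp, std::max(gamma - 1.0, 0.0)) * std::log(ptc)
                       - std::pow(omp, gamma) / ptc);
  if (gamma == 0.0) dldpt = -at / ptc;
  double dptdz = (y > 0.5) ? pprob * (1.0 - pprob) : -pprob * (1.0 - pprob);
  dz_out = dldpt * dptdz;
  return loss;
}

// ------------------------------------------------------------ per-sample work

struct LossOpt { double gamma, a1, a0; };

static rowvec sample_score(PMap& p, const Data& dt, int i, const Cfg& c) {
  mat tok; vec mask;
  embed_fwd(p, dt, i, c, tok, mask);
  EncCache ec; encode_fwd(p, tok, mask, false, c, ec);
  DecCache dc; decode_fwd(p, dt, i, ec.enc, mask, c, dc);
  return dc.s;
}

// fine-tuning: focal loss over the N-drug multi-hot target
static double sample_grad_finetune(PMap& p, PMap& g, const Data& dt, int i,
                                   const Cfg& c, const LossOpt& lo, double wscale) {
  mat tok; vec mask;
  embed_fwd(p, dt, i, c, tok, mask);
  EncCache ec; encode_fwd(p, tok, mask, false, c, ec);
  DecCache dc; decode_fwd(p, dt, i, ec.enc, mask, c, dc);
  rowvec dz(c.N);
  double L = 0.0;
  for (int j = 0; j < c.N; ++j) {
    double dzj;
    L += focal_term(dc.s(j), dt.target(j, i), lo.gamma, lo.a1, lo.a0, dzj);
    dz(j) = dzj / c.N * wscale;
  }
  L /= c.N;
  mat dEnc = decode_bwd(p, g, dz, dt, i, ec.enc, c, dc);
  mat dTok = encode_bwd(p, g, dEnc, c, ec);
  embed_bwd(p, g, dTok, dt, i, c);
  return L;
}

// pretraining: causal encoder, auxiliary next-observation heads.
// At every observed week position, predict each channel's next observed
// value (standardized-residual MSE), the next categorical level, and the
// drug set of the next visit week (focal loss). "Next" is the next
// OBSERVED occurrence after the position: under irregular sampling the
// literally adjacent week is almost always empty.
static void sample_grad_pretrain(PMap& p, PMap& g, const Data& dt, int i, const Cfg& c,
                                 const LossOpt& lo, double wscale,
                                 double& num_out, double& cat_out) {
  mat tok; vec mask;
  embed_fwd(p, dt, i, c, tok, mask);
  EncCache ec; encode_fwd(p, tok, mask, true, c, ec);
  const mat& enc = ec.enc;
  const mat& sc = p["num_scale"];   // 1 x Cn, fixed
  const mat& mu_ = p["num_mu"];     // 1 x Cn, fixed

  // nxt*(row, w): 0-based index of the next observation strictly after
  // 0-based week w, or -1
  arma::imat nxt_num(std::max(c.Cn, 1), c.T);
  arma::imat nxt_cat(std::max(c.Cc, 1), c.T);
  arma::ivec nxt_vis(c.T);
  {
    for (int ch = 0; ch < c.Cn; ++ch) {
      int nx = -1;
      for (int t = c.T - 1; t >= 0; --t) {
        nxt_num(ch, t) = nx;
        if (dt.numm(ch, t, i) > 0.5) nx = t;
      }
    }
    for (int ch = 0; ch < c.Cc; ++ch) {
      int nx = -1;
      for (int t = c.T - 1; t >= 0; --t) {
        nxt_cat(ch, t) = nx;
        if ((int)dt.catv(ch, t, i) > 0) nx = t;
      }
    }
    int nx = -1;
    for (int t = c.T - 1; t >= 0; --t) {
      nxt_vis(t) = nx;
      if (dt.weekmask(t, i) > 0.5) nx = t;
    }
  }

  std::vector<int> pos;             // context positions (1-based row index)
  for (int w = 1; w <= c.T; ++w)
    if (mask(w) > 0.5 && nxt_vis(w - 1) >= 0) pos.push_back(w);
  num_out = 0.0; cat_out = 0.0;
  if (pos.empty()) return;

  int npos = (int)pos.size();
  double numloss = 0.0; int numcount = 0;
  double drugloss = 0.0;
  double catloss = 0.0; int catcount = 0;

  // first pass: predictions, losses, unscaled head-input grads per position
  mat dY(npos, c.Cn, arma::fill::zeros);               // numeric dL/dyhat (unscaled)
  mat dZd(npos, c.N, arma::fill::zeros);               // drug logit grads (unscaled)
  std::vector<mat> zc_grad(c.Cc);                      // categorical logit grads
  for (int ch = 0; ch < c.Cc; ++ch)
    zc_grad[ch] = mat(npos, c.K[ch], arma::fill::zeros);

  for (int q = 0; q < npos; ++q) {
    int w = pos[q];
    int t0 = w - 1;                  // 0-based week of this position
    rowvec h = enc.row(w);
    rowvec yh = h * p["aux_reg_W"] + p["aux_reg_b"].row(0);
    for (int ch = 0; ch < c.Cn; ++ch) {
      int tn = nxt_num(ch, t0);
      if (tn >= 0) {
        // the head predicts the standardized value; raw targets are mapped
        // with the frozen training mean/SD so every channel is O(1)
        double r = yh(ch) - (dt.numv(ch, tn, i) - mu_(0, ch)) / sc(0, ch);
        numloss += r * r;
        numcount++;
        dY(q, ch) = 2.0 * r;
      }
    }
    int tv = nxt_vis(t0);
    rowvec zd = h * p["aux_drug_W"] + p["aux_drug_b"].row(0);
    for (int j = 0; j < c.N; ++j) {
      double pj = 1.0 / (1.0 + std::exp(-zd(j)));
      double dzj;
      drugloss += focal_term(pj, dt.drugs(j, tv, i), lo.gamma, lo.a1, lo.a0, dzj);
      dZd(q, j) = dzj;
    }
    for (int ch = 0; ch < c.Cc; ++ch) {
      int tn = nxt_cat(ch, t0);
      int k = tn >= 0 ? (int)dt.catv(ch, tn, i) : 0;
      if (k > 0) {
        std::string nm = "aux_cat" + std::to_string(ch + 1);
        rowvec zc = h * p[nm + "_W"] + p[nm + "_b"].row(0);
        rowvec pr = arma::exp(zc - zc.max());
        pr /= arma::accu(pr);
        double q1 = std::min(std::max(pr(k - 1), P_EPS), 1.0 - P_EPS);
        catloss += -std::pow(1.0 - q1, lo.gamma) * std::log(q1);
        catcount++;
        double dldq = lo.gamma * std::pow(1.0 - q1, std::max(lo.gamma - 1.0, 0.0)) * std::log(q1)
                      - std::pow(1.0 - q1, lo.gamma) / q1;
        if (lo.gamma == 0.0) dldq = -1.0 / q1;
        for (int j2 = 0; j2 < c.K[ch]; ++j2) {
          double d = (j2 == k - 1) ? 1.0 : 0.0;
          zc_grad[ch](q, j2) = dldq * q1 * (d - pr(j2));
        }
      }
    }
  }

  double nnum = std::max(1, numcount);
  double ncat = std::max(1, catcount);
  num_out = numloss / nnum;
  cat_out = drugloss / (c.N * npos) + catloss / ncat;

  // second pass: scale and backpropagate into the encoder state
  mat dEnc(enc.n_rows, enc.n_cols, arma::fill::zeros);
  for (int q = 0; q < npos; ++q) {
    int w = pos[q];
    rowvec h = enc.row(w);
    rowvec dyh = dY.row(q) / nnum * wscale;
    g["aux_reg_W"] += h.t() * dyh;
    g["aux_reg_b"] += dyh;
    dEnc.row(w) += dyh * p["aux_reg_W"].t();
    rowvec dzd = dZd.row(q) / (c.N * npos) * wscale;
    g["aux_drug_W"] += h.t() * dzd;
    g["aux_drug_b"] += dzd;
    dEnc.row(w) += dzd * p["aux_drug_W"].t();
    for (int ch = 0; ch < c.Cc; ++ch) {
      rowvec dzc = zc_grad[ch].row(q) / ncat * wscale;
      if (arma::accu(arma::abs(dzc)) == 0.0) continue;
      std::string nm = "aux_cat" + std::to_string(ch + 1);
      g[nm + "_W"] += h.t() * dzc;
      g[nm + "_b"] += dzc;
      dEnc.row(w) += dzc * p[nm + "_W"].t();
    }
  }
  mat dTok = encode_bwd(p, g, dEnc, c, ec);
  embed_bwd(p, g, dTok, dt, i, c);
}

// ----------------------------------------------------------------- micro AUC

static double micro_auc_core(const std::vector<double>& sc, const std::vector<int>& lab) {
  int n = (int)sc.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) { return sc[a] < sc[b]; });
  std::vector<double> rank(n);
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && sc[ord[j + 1]] == sc[ord[i]]) ++j;
    double avg = 0.5 * (i + j) + 1.0;   // average rank (1-based)
    for (int k2 = i; k2 <= j; ++k2) rank[ord[k2]] = avg;
    i = j + 1;
  }
  double sumpos = 0.0;
  long n1 = 0;
  for (int k2 = 0; k2 < n; ++k2)
    if (lab[k2] == 1) { sumpos += rank[k2]; ++n1; }
  long n0 = n - n1;
  if (n1 == 0 || n0 == 0) return NA_REAL;
  return (sumpos - (double)n1 * (n1 + 1) / 2.0) / ((double)n1 * (double)n0);
}

// ------------------------------------------------------------------- exports

// [[Rcpp::export]]
arma::mat cpp_score(List params, List data, List cfg) {
  PMap p = read_params(params);
  Data dt = read_data(data);
  Cfg c = read_cfg(cfg);
  mat out(dt.n, c.N);
  for (int i = 0; i < dt.n; ++i)
    out.row(i) = sample_score(p, dt, i, c);
  return out;
}

// [[Rcpp::export]]
List cpp_embed(List params, List data, List cfg, int i) {
  PMap p = read_params(params);
  Data dt = read_data(data);
  Cfg c = read_cfg(cfg);
  if (i < 1 || i > dt.n) stop("sample index out of range");
  mat tok; vec mask;
  embed_fwd(p, dt, i - 1, c, tok, mask);
  return List::create(_["tokens"] = tok, _["mask"] = mask);
}

// [[Rcpp::export]]
List cpp_encode_tokens(List params, arma::mat tokens, arma::vec mask, List cfg,
                       bool causal, bool return_attn) {
  PMap p = read_params(params);
  Cfg c = read_cfg(cfg);
  EncCache ec;
  encode_fwd(p, tokens, mask, causal, c, ec);
  List out = List::create(_["states"] = ec.enc, _["mask"] = mask);
  if (return_attn) {
    List aw;
    for (int l = 0; l < c.Lenc; ++l) {
      List lw;
      for (int h = 0; h < c.H; ++h) lw.push_back(wrap(ec.B[l].at.P[h]));
      aw.push_back(lw);
    }
    out["attention"] = aw;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_encode(List params, List data, List cfg, int i, bool causal) {
  PMap p = read_params(params);
  Data dt = read_data(data);
  Cfg c = read_cfg(cfg);
  if (i < 1 || i > dt.n) stop("sample index out of range");
  mat tok; vec mask;
  embed_fwd(p, dt, i - 1, c, tok, mask);
  EncCache ec;
  encode_fwd(p, tok, mask, causal, c, ec);
  return List::create(_["states"] = ec.enc, _["mask"] = mask);
}

// [[Rcpp::export]]
List cpp_decode(List params, List data, List cfg, int i, arma::mat enc, arma::vec mask) {
  PMap p = read_params(params);
  Data dt = read_data(data);
  Cfg c = read_cfg(cfg);
  if (i < 1 || i > dt.n) stop("sample index out of range");
  DecCache dc;
  decode_fwd(p, dt, i - 1, enc, mask, c, dc);
  return List::create(_["scores"] = NumericVector(dc.s.begin(), dc.s.end()));
}

// [[Rcpp::export]]
List cpp_grad(List params, List data, List cfg, IntegerVector idx, std::string mode,
              double gamma, double alpha, bool alpha_on) {
  PMap p = read_params(params);
  Data dt = read_data(data);
  Cfg c = read_cfg(cfg);
  PMap g = zeros_like(p);
  LossOpt lo;
  lo.gamma = gamma;
  lo.a1 = alpha_on ? alpha : 1.0;
  lo.a0 = alpha_on ? 1.0 - alpha : 1.0;
  int B = idx.size();
  if (B == 0) stop("empty sample set");
  double loss = 0.0, numl = 0.0, catl = 0.0;
  for (int k = 0; k < B; ++k) {
    int i = idx[k] - 1;
    if (i < 0 || i >= dt.n) stop("sample index out of range");
    if (mode == "finetune") {
      loss += sample_grad_finetune(p, g, dt, i, c, lo, 1.0 / B);
    } else {
      double a, b2;
      sample_grad_pretrain(p, g, dt, i, c, lo, 1.0 / B, a, b2);
      numl += a; catl += b2;
      loss += a + b2;
    }
  }
  return List::create(_["loss"] = loss / B,
                      _["numeric"] = numl / B,
                      _["categorical"] = catl / B,
                      _["grads"] = params_to_list(g));
}

// [[Rcpp::export]]
double cpp_micro_auc(NumericVector scores, IntegerVector labels) {
  std::vector<double> sc(scores.begin(), scores.end());
  std::vector<int> lab(labels.begin(), labels.end());
  return micro_auc_core(sc, lab);
}

// Full optimization loop.  tcfg fields:
//   mode ("pretrain"/"finetune"), lr, beta1, beta2, eps, epochs, batch,
//   gamma, alpha, alpha_on, freeze_encoder,
//   perm: ntrain x epochs integer matrix of 1-based data indices,
//   val:  1-based indices used for per-epoch micro-AUC checkpoint selection
//         (finetune only; empty disables checkpointing).
// [[Rcpp::export]]
List cpp_train(List params, List data, List cfg, List tcfg) {
  PMap p = read_params(params);
  Data dt = read_data(data);
  Cfg c = read_cfg(cfg);
  std::string mode = as<std::string>(tcfg["mode"]);
  double lr = as<double>(tcfg["lr"]);
  double b1 = as<double>(tcfg["beta1"]);
  double b2 = as<double>(tcfg["beta2"]);
  double ad_eps = as<double>(tcfg["eps"]);
  int epochs = as<int>(tcfg["epochs"]);
  int batch = as<int>(tcfg["batch"]);
  bool freeze = as<bool>(tcfg["freeze_encoder"]);
  LossOpt lo;
  lo.gamma = as<double>(tcfg["gamma"]);
  double alpha = as<double>(tcfg["alpha"]);
  bool alpha_on = as<bool>(tcfg["alpha_on"]);
  lo.a1 = alpha_on ? alpha : 1.0;
  lo.a0 = alpha_on ? 1.0 - alpha : 1.0;
  IntegerMatrix perm = tcfg["perm"];
  IntegerVector val = tcfg["val"];
  int ntr = perm.nrow();
  if (ntr == 0) stop("empty sample set");
  if (perm.ncol() < epochs) stop("permutation matrix has fewer columns than epochs");

  std::set<std::string> fixed;
  fixed.insert("pe");
  fixed.insert("num_scale");
  fixed.insert("num_mu");

  PMap m = zeros_like(p), v = zeros_like(p);
  std::vector<double> trace(epochs), numtrace(epochs), cattrace(epochs), valtrace;
  PMap best = p;
  double best_auc = -1.0;
  int best_epoch = -1;
  long tstep = 0;

  for (int e = 0; e < epochs; ++e) {
    double eloss = 0.0, enum_ = 0.0, ecat = 0.0;
    int nb = 0;
    for (int start = 0; start < ntr; start += batch) {
      int end = std::min(start + batch, ntr);
      int bs = end - start;
      PMap g = zeros_like(p);
      double bl = 0.0, bnum = 0.0, bcat = 0.0;
      for (int k = start; k < end; ++k) {
        int i = perm(k, e) - 1;
        if (i < 0 || i >= dt.n) stop("permutation index out of range");
        if (mode == "finetune") {
          bl += sample_grad_finetune(p, g, dt, i, c, lo, 1.0 / bs) / bs;
        } else {
          double a, b_;
          sample_grad_pretrain(p, g, dt, i, c, lo, 1.0 / bs, a, b_);
          bnum += a / bs; bcat += b_ / bs;
        }
      }
      if (mode != "finetune") bl = bnum + bcat;
      eloss += bl; enum_ += bnum; ecat += bcat; nb++;
      ++tstep;
      double bc1 = 1.0 - std::pow(b1, (double)tstep);
      double bc2 = 1.0 - std::pow(b2, (double)tstep);
      for (PMap::iterator it = p.begin(); it != p.end(); ++it) {
        const std::string& nm = it->first;
        if (fixed.count(nm)) continue;
        if (freeze && mode == "finetune" &&
            (nm.rfind("enc", 0) == 0 || nm.rfind("num_", 0) == 0 ||
             nm.rfind("cat", 0) == 0 || nm == "drug_emb"))
          continue;
        mat& gm = g[nm];
        mat& mm = m[nm];
        mat& vm = v[nm];
        mm = b1 * mm + (1.0 - b1) * gm;
        vm = b2 * vm + (1.0 - b2) * (gm % gm);
        it->second -= lr * (mm / bc1) / (arma::sqrt(vm / bc2) + ad_eps);
      }
    }
    trace[e] = eloss / nb;
    numtrace[e] = enum_ / nb;
    cattrace[e] = ecat / nb;
    if (mode == "finetune" && val.size() > 0) {
      std::vector<double> sc;
      std::vector<int> lab;
      sc.reserve((size_t)val.size() * c.N);
      lab.reserve((size_t)val.size() * c.N);
      for (int k = 0; k < val.size(); ++k) {
        int i = val[k] - 1;
        rowvec s = sample_score(p, dt, i, c);
        for (int j = 0; j < c.N; ++j) {
          sc.push_back(s(j));
          lab.push_back(dt.target(j, i) > 0.5 ? 1 : 0);
        }
      }
      double auc = micro_auc_core(sc, lab);
      valtrace.push_back(auc);
      if (!ISNAN(auc) && auc > best_auc) {
        best_auc = auc;
        best = p;
        best_epoch = e + 1;
      }
    }
    Rcpp::checkUserInterrupt();
  }

  bool use_best = (mode == "finetune" && val.size() > 0 && best_epoch > 0);
  return List::create(
      _["params"] = params_to_list(use_best ? best : p),
      _["final_params"] = params_to_list(p),
      _["loss"] = wrap(trace),
      _["numeric_loss"] = wrap(numtrace),
      _["categorical_loss"] = wrap(cattrace),
      _["val_auc"] = wrap(valtrace),
      _["best_epoch"] = best_epoch);
}
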
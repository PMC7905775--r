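// Arbitrary-precision rational arithmetic with a "p/q" string interface.
//
// Numbers cross the R/C++ boundary as canonical decimal strings "p" or "p/q"
// (q > 0, gcd(|p|, q) = 1).  Magnitudes are stored little-endian in base 1e9.
// Only the operations the package needs are implemented: ring/field ops,
// comparison, exact square root, polynomial convolution and Horner evaluation.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>

using namespace Rcpp;

namespace {

typedef std::vector<uint32_t> Limbs; // base 1e9, little-endian
const uint32_t BASE = 1000000000u;

struct BigInt {
  int sign;              // -1, 0, 1
  Limbs d;               // empty iff sign == 0
  BigInt() : sign(0) {}
};

void trim(Limbs &a) { while (!a.empty() && a.back() == 0) a.pop_back(); }

int cmp_mag(const Limbs &a, const Limbs &b) {
  if (a.size() != b.size()) return a.size() < b.size() ? -1 : 1;
  for (size_t i = a.size(); i-- > 0;)
    if (a[i] != b[i]) return a[i] < b[i] ? -1 : 1;
  return 0;
}

Limbs add_mag(const Limbs &a, const Limbs &b) {
  Limbs r;
  r.reserve(std::max(a.size(), b.size()) + 1);
  uint32_t carry = 0;
  for (size_t i = 0; i < std::max(a.size(), b.size()); ++i) {
    uint32_t s = carry;
    if (i < a.size()) s += a[i];
    if (i < b.size()) s += b[i];
    if (s >= BASE) { s -= BASE; carry = 1; } else carry = 0;
    r.push_back(s);
  }
  if (carry) r.push_back(carry);
  return r;
}

// requires |a| >= |b|
Limbs sub_mag(const Limbs &a, const Limbs &b) {
  Limbs r;
  r.reserve(a.size());
  int64_t borrow = 0;
  for (size_t i = 0; i < a.size(); ++i) {
    int64_t s = (int64_t)a[i] - borrow - (i < b.size() ? (int64_t)b[i] : 0);
    if (s < 0) { s += BASE; borrow = 1; } else borrow = 0;
    r.push_back((uint32_t)s);
  }
  trim(r);
  return r;
}

Limbs mul_mag(const Limbs &a, const Limbs &b) {
  if (a.empty() || b.empty()) return Limbs();
  Limbs r(a.size() + b.size(), 0);
  for (size_t i = 0; i < a.size(); ++i) {
    uint64_t carry = 0;
    for (size_t j = 0; j < b.size(); ++j) {
      uint64_t cur = r[i + j] + (uint64_t)a[i] * b[j] + carry;
      r[i + j] = (uint32_t)(cur % BASE);
      carry = cur / BASE;
    }
    size_t k = i + b.size();
    while (carry) {
      uint64_t cur = r[k] + carry;
      r[k] = (uint32_t)(cur % BASE);
      carry = cur / BASE;
      ++k;
    }
  }
  trim(r);
  return r;
}

Limbs mul_small(const Limbs &a, uint32_t m) {
  if (a.empty() || m == 0) return Limbs();
  Limbs r;
  r.reserve(a.size() + 1);
  uint64_t carry = 0;
  for (size_t i = 0; i < a.size(); ++i) {
    uint64_t cur = (uint64_t)a[i] * m + carry;
    r.push_back((uint32_t)(cur % BASE));
    carry = cur / BASE;
  }
  while (carry) { r.push_back((uint32_t)(carry % BASE)); carry /= BASE; }
  return r;
}

// schoolbook long division of magnitudes: a = q*b + r, b != 0
void divmod_mag(const Limbs &a, const Limbs &b, Limbs &q, Limbs &r) {
  q.assign(a.size(), 0);
  r.clear();
  for (size_t i = a.size(); i-- > 0;) {
    // r = r * BASE + a[i]
    r.insert(r.begin(), a[i]);
    trim(r);
    if (cmp_mag(r, b) < 0) { q[i] = 0; continue; }
    // binary search for the quotient digit
    uint32_t lo = 1, hi = BASE - 1, best = 0;
    while (lo <= hi) {
      uint32_t mid = lo + (hi - lo) / 2;
      if (cmp_mag(mul_small(b, mid), r) <= 0) { best = mid; lo = mid + 1; }
      else { if (mid == 0) break; hi = mid - 1; }
    }
    q[i] = best;
    r = sub_mag(r, mul_small(b, best));
  }
  trim(q);
}

Limbs gcd_mag(Limbs a, Limbs b) {
  while (!b.empty()) {
    Limbs q, r;
    divmod_mag(a, b, q, r);
    a.swap(b);
    b.swap(r);
  }
  return a;
}

bool is_one(const Limbs &a) { return a.size() == 1 && a[0] == 1; }

BigInt make_int(int sign, Limbs d) {
  BigInt x;
  trim(d);
  x.d = d;
  x.sign = x.d.empty() ? 0 : sign;
  return x;
}

BigInt add_int(const BigInt &a, const BigInt &b) {
  if (a.sign == 0) return b;
  if (b.sign == 0) return a;
  if (a.sign == b.sign) return make_int(a.sign, add_mag(a.d, b.d));
  int c = cmp_mag(a.d, b.d);
  if (c == 0) return BigInt();
  if (c > 0) return make_int(a.sign, sub_mag(a.d, b.d));
  return make_int(b.sign, sub_mag(b.d, a.d));
}

BigInt neg_int(const BigInt &a) { BigInt r = a; r.sign = -r.sign; return r; }

BigInt mul_int(const BigInt &a, const BigInt &b) {
  if (a.sign == 0 || b.sign == 0) return BigInt();
  return make_int(a.sign * b.sign, mul_mag(a.d, b.d));
}

std::string mag_to_string(const Limbs &a) {
  if (a.empty()) return "0";
  std::string s = std::to_string(a.back());
  char buf[16];
  for (size_t i = a.size() - 1; i-- > 0;) {
    snprintf(buf, sizeof(buf), "%09u", a[i]);
    s += buf;
  }
  return s;
}

Limbs mag_from_string(const std::string &s, size_t from, size_t to) {
  Limbs r;
  size_t len = to - from;
  if (len == 0) stop("empty integer in rational literal");
  size_t nlimb = (len + 8) / 9;
  r.reserve(nlimb);
  size_t end = to;
  while (end > from) {
    size_t start = end >= from + 9 ? end - 9 : from;
    uint32_t v = 0;
    for (size_t i = start; i < end; ++i) {
      char c = s[i];
      if (c < '0' || c > '9') stop("invalid character in rational literal '%s'", s.c_str());
      v = v * 10 + (uint32_t)(c - '0');
    }
    r.push_back(v);
    end = start;
  }
  trim(r);
  return r;
}

double mag_to_double(const Limbs &a, int &exp10) {
  // value ~= result * 10^exp10, using the top limbs only
  exp10 = 0;
  if (a.empty()) return 0.0;
  double v = 0.0;
  size_t take = a.size() < 3 ? a.size() : 3;
  for (size_t i = 0; i < take; ++i) v = v * 1e9 + (double)a[a.size() - 1 - i];
  exp10 = 9 * (int)(a.size() - take);
  return v;
}

struct Rat {
  BigInt num;
  Limbs den; // positive magnitude; "1" for integers; num.sign carries sign
};

void reduce(Rat &x) {
  if (x.den.empty()) stop("zero denominator");
  if (x.num.sign == 0) { x.den.assign(1, 1); return; }
  if (!is_one(x.den)) {
    Limbs g = gcd_mag(x.num.d, x.den);
    if (!is_one(g)) {
      Limbs q, r;
      divmod_mag(x.num.d, g, q, r);
      x.num.d = q;
      divmod_mag(x.den, g, q, r);
      x.den = q;
    }
  }
}

Rat rat_parse(const std::string &s) {
  Rat x;
  if (s.empty()) stop("empty rational literal");
  size_t pos = 0;
  int sign = 1;
  if (s[0] == '-') { sign = -1; pos = 1; }
  else if (s[0] == '+') pos = 1;
  size_t slash = s.find('/', pos);
  if (slash == std::string::npos) {
    x.num = make_int(sign, mag_from_string(s, pos, s.size()));
    x.den.assign(1, 1);
  } else {
    x.num = make_int(sign, mag_from_string(s, pos, slash));
    size_t dpos = slash + 1;
    int dsign = 1;
    if (dpos < s.size() && s[dpos] == '-') { dsign = -1; ++dpos; }
    x.den = mag_from_string(s, dpos, s.size());
    if (x.den.empty()) stop("zero denominator in '%s'", s.c_str());
    if (dsign < 0) x.num.sign = -x.num.sign;
  }
  reduce(x);
  return x;
}

std::string rat_format(const Rat &x) {
  std::string s;
  if (x.num.sign < 0) s += "-";
  s += mag_to_string(x.num.d);
  if (!is_one(x.den)) {
    s += "/";
    s += mag_to_string(x.den);
  }
  return s;
}

Rat rat_add(const Rat &a, const Rat &b) {
  Rat r;
  BigInt ad = make_int(a.num.sign, mul_mag(a.num.d, b.den));
  BigInt bc = make_int(b.num.sign, mul_mag(b.num.d, a.den));
  r.num = add_int(ad, bc);
  r.den = mul_mag(a.den, b.den);
  reduce(r);
  return r;
}

Rat rat_neg(const Rat &a) { Rat r = a; r.num.sign = -r.num.sign; return r; }

Rat rat_mul(const Rat &a, const Rat &b) {
  Rat r;
  r.num = mul_int(a.num, b.num);
  r.den = mul_mag(a.den, b.den);
  reduce(r);
  return r;
}

Rat rat_div(const Rat &a, const Rat &b) {
  if (b.num.sign == 0) stop("division by zero rational");
  Rat r;
  r.num = make_int(a.num.sign * b.num.sign, mul_mag(a.num.d, b.den));
  r.den = mul_mag(a.den, b.num.d);
  reduce(r);
  return r;
}

int rat_cmp(const Rat &a, const Rat &b) {
  BigInt lhs = make_int(a.num.sign, mul_mag(a.num.d, b.den));
  BigInt rhs = make_int(b.num.sign, mul_mag(b.num.d, a.den));
  BigInt d = add_int(lhs, neg_int(rhs));
  return d.sign;
}

double rat_double(const Rat &a) {
  if (a.num.sign == 0) return 0.0;
  int en, ed;
  double vn = mag_to_double(a.num.d, en);
  double vd = mag_to_double(a.den, ed);
  double v = (vn / vd) * std::pow(10.0, (double)(en - ed));
  return a.num.sign < 0 ? -v : v;
}

// exact integer square root if perfect square, else empty
bool mag_sqrt(const Limbs &a, Limbs &root) {
  if (a.empty()) { root.clear(); return true; }
  // Newton iteration x_{k+1} = (x_k + a / x_k) / 2 starting from x_0 = a
  Limbs x = a;
  Limbs two(1, 2);
  for (int iter = 0; iter < 4000; ++iter) {
    Limbs q, r;
    divmod_mag(a, x, q, r);
    Limbs s = add_mag(x, q);
    Limbs nx, rem;
    divmod_mag(s, two, nx, rem);
    if (cmp_mag(nx, x) >= 0) break;
    x = nx;
  }
  if (cmp_mag(mul_mag(x, x), a) == 0) { root = x; return true; }
  return false;
}

Rat rat_get(const CharacterVector &v, R_xlen_t i) {
  if (CharacterVector::is_na(v[i])) stop("NA rational");
  return rat_parse(as<std::string>(v[i]));
}

} // namespace

// [[Rcpp::export(name = ".bq_norm")]]
CharacterVector bq_norm(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) out[i] = rat_format(rat_get(x, i));
  return out;
}

typedef Rat (*RatBin)(const Rat &, const Rat &);

static Rat rat_sub(const Rat &a, const Rat &b) { return rat_add(a, rat_neg(b)); }

static CharacterVector bq_binop(CharacterVector x, CharacterVector y, RatBin fun) {
  R_xlen_t n = std::max(x.size(), y.size());
  if (x.size() == 0 || y.size() == 0) return CharacterVector(0);
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = rat_format(fun(rat_get(x, i % x.size()), rat_get(y, i % y.size())));
  return out;
}

// [[Rcpp::export(name = ".bq_add")]]
CharacterVector bq_add(CharacterVector x, CharacterVector y) { return bq_binop(x, y, rat_add); }

// [[Rcpp::export(name = ".bq_sub")]]
CharacterVector bq_sub(CharacterVector x, CharacterVector y) { return bq_binop(x, y, rat_sub); }

// [[Rcpp::export(name = ".bq_mul")]]
CharacterVector bq_mul(CharacterVector x, CharacterVector y) { return bq_binop(x, y, rat_mul); }

// [[Rcpp::export(name = ".bq_div")]]
CharacterVector bq_div(CharacterVector x, CharacterVector y) { return bq_binop(x, y, rat_div); }

// [[Rcpp::export(name = ".bq_neg")]]
CharacterVector bq_neg(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) out[i] = rat_format(rat_neg(rat_get(x, i)));
  return out;
}

// [[Rcpp::export(name = ".bq_cmp")]]
IntegerVector bq_cmp(CharacterVector x, CharacterVector y) {
  R_xlen_t n = std::max(x.size(), y.size());
  if (x.size() == 0 || y.size() == 0) return IntegerVector(0);
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = rat_cmp(rat_get(x, i % x.size()), rat_get(y, i % y.size()));
  return out;
}

// [[Rcpp::export(name = ".bq_as_double")]]
NumericVector bq_as_double(CharacterVector x) {
  NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) out[i] = rat_double(rat_get(x, i));
  return out;
}

// [[Rcpp::export(name = ".bq_sum")]]
CharacterVector bq_sum(CharacterVector x) {
  Rat acc = rat_parse("0");
  for (R_xlen_t i = 0; i < x.size(); ++i) acc = rat_add(acc, rat_get(x, i));
  return CharacterVector::create(rat_format(acc));
}

// [[Rcpp::export(name = ".bq_prod")]]
CharacterVector bq_prod(CharacterVector x) {
  Rat acc = rat_parse("1");
  for (R_xlen_t i = 0; i < x.size(); ++i) acc = rat_mul(acc, rat_get(x, i));
  return CharacterVector::create(rat_format(acc));
}

// polynomial convolution, coefficients ascending
// [[Rcpp::export(name = ".bq_polymul")]]
CharacterVector bq_polymul(CharacterVector a, CharacterVector b) {
  if (a.size() == 0 || b.size() == 0) return CharacterVector(0);
  std::vector<Rat> ra(a.size()), rb(b.size());
  for (R_xlen_t i = 0; i < a.size(); ++i) ra[i] = rat_get(a, i);
  for (R_xlen_t i = 0; i < b.size(); ++i) rb[i] = rat_get(b, i);
  std::vector<Rat> rc(a.size() + b.size() - 1, rat_parse("0"));
  for (size_t i = 0; i < ra.size(); ++i)
    for (size_t j = 0; j < rb.size(); ++j)
      rc[i + j] = rat_add(rc[i + j], rat_mul(ra[i], rb[j]));
  CharacterVector out(rc.size());
  for (size_t i = 0; i < rc.size(); ++i) out[i] = rat_format(rc[i]);
  return out;
}

// exact Horner evaluation of an ascending-coefficient polynomial
// [[Rcpp::export(name = ".bq_polyeval")]]
CharacterVector bq_polyeval(CharacterVector coef, CharacterVector x) {
  Rat xv = rat_get(x, 0);
  Rat acc = rat_parse("0");
  for (R_xlen_t i = coef.size(); i-- > 0;)
    acc = rat_add(rat_mul(acc, xv), rat_get(coef, i));
  return CharacterVector::create(rat_format(acc));
}

// exact square root: NA where the argument is negative or not a perfect square
// [[Rcpp::export(name = ".bq_sqrt")]]
CharacterVector bq_sqrt(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    Rat v = rat_get(x, i);
    if (v.num.sign < 0) { out[i] = NA_STRING; continue; }
    Limbs rn, rd;
    if (!mag_sqrt(v.num.d, rn) || !mag_sqrt(v.den, rd)) { out[i] = NA_STRING; continue; }
    Rat r;
    r.num = make_int(v.num.sign == 0 ? 0 : 1, rn);
    r.den = rd.empty() ? Limbs(1, 1) : rd;
    out[i] = rat_format(r);
  }
  return out;
}
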